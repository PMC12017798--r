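#!/usr/bin/env Rscript
# Stage 3: subgenome composition statistics.
#
# Genome-wide subgenome shares, per-cluster subgenome shares of expressed
# genes, expressed fractions by homoeolog-group class, and the per-cluster
# one-way ANOVA of expressed-gene mean expression across subgenomes
# (each of LF/MF1/MF2 contrasted against UG).

suppressPackageStartupMessages(library(triadbias))

cm <- read_10x("results/data/sim")
cm <- read_clusters("results/data/sim/clusters.tsv", cm)
cm <- qc_filter(cm, qc_thresholds(min_genes = 200, max_genes = 4000))
homology <- read_homology("results/data/sim/homology.tsv")
profile <- pseudobulk(normalize_counts(cm), cm$clusters,
                      detect_expressed(cm))

comp <- genome_composition(homology)
write.table(comp, "results/genome_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("genome composition (%):",
    paste(comp$subgenome, comp$percent, collapse = ", "), "\n")

ec <- expressed_composition(profile, homology)
write.table(ec, "results/expressed_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mean expressed share by subgenome across clusters:\n")
print(round(tapply(ec$proportion, ec$subgenome, mean), 3))

cf <- expressed_fraction_by_class(profile, homology)
write.table(cf, "results/class_fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("mean expressed fraction by group class:\n")
print(round(tapply(cf$fraction, cf$class, mean), 3))

anova_tab <- do.call(rbind, lapply(profile$clusters, function(cl) {
  a <- subgenome_anova(profile, homology, cl)
  data.frame(cluster = cl, F = a$F, p = a$p,
             t(setNames(a$group_means, paste0("mean_",
                                              names(a$group_means)))))
}))
write.table(anova_tab, "results/anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("clusters with subgenome effect at alpha = 0.05:",
    sum(anova_tab$p < 0.05), "of", nrow(anova_tab), "\n")
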