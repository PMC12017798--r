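#!/usr/bin/env Rscript
# Stage 5: cluster-enriched marker genes.
#
# Wilcoxon rank-sum test of each gene, cluster vs rest, gated at
# log2FC >= 0.58 and min.pct = 0.25, BH-adjusted; compares calls against
# the simulation's planted marker genes.

suppressPackageStartupMessages(library(triadbias))

cm <- read_10x("results/data/sim")
cm <- read_clusters("results/data/sim/clusters.tsv", cm)
cm <- qc_filter(cm, qc_thresholds(min_genes = 200, max_genes = 4000))
norm <- normalize_counts(cm)

mk <- find_markers(norm, cm$clusters, marker_config(logfc_threshold = 0.58,
                                                    min_pct = 0.25))
write.table(mk, "results/markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- mk[mk$q_value < 0.05, ]
cat("tested", nrow(mk), "gene-cluster pairs;", nrow(sig),
    "significant at FDR 0.05\n")

truth <- jsonlite::read_json("results/data/sim/truth.json",
                             simplifyVector = TRUE)$markers
hit <- merge(truth, sig, by = c("gene", "cluster"))
cat("planted markers:", nrow(truth), "; recovered at FDR 0.05:", nrow(hit),
    sprintf("(%.1f%%)\n", 100 * nrow(hit) / nrow(truth)))
cat("top 5 calls:\n")
print(head(sig[order(sig$q_value), c("gene", "cluster", "log2fc",
                                     "pct_in", "pct_out", "q_value")], 5))
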