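## Round half away from zero to `digits` decimals (printed percentages use
## this convention; base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify homoeolog groups into triads, duplets, monads and UG
#'
#' Groups are classified by their per-subgenome membership pattern: a triad
#' has exactly one member on each of LF, MF1 and MF2 (1:1:1); a duplet has
#' two subgenomes represented (1:1:0, 1:0:1 or 0:1:1); a monad has a single
#' member (genes without homoeologs); UG genes carry no subgenome assignment.
#'
#' @param table a [homology_table()].
#' @return list with `gene_class` (named character vector, per gene),
#'   `group_class` (named, per non-empty group id) and `counts`
#'   (n_triads, n_duplets, n_monads, n_ug).
#' @export
classify_groups <- function(table) {
  stopifnot(inherits(table, "homology_table"))
  gene_class <- stats::setNames(rep(NA_character_, nrow(table)),
                                table$gene_id)
  is_ug <- table$subgenome == "UG"
  gene_class[is_ug] <- "ungrouped"
  # genes on a subgenome but without a group id have no homoeologs
  lone <- !is_ug & table$group_id == ""
  gene_class[lone] <- "monad"
  grouped <- table[!is_ug & table$group_id != "", ]
  group_class <- character(0)
  if (nrow(grouped)) {
    size <- table(grouped$group_id)
    group_class <- stats::setNames(
      c("monad", "duplet", "triad")[as.integer(size)], names(size))
    gene_class[grouped$gene_id] <- group_class[grouped$group_id]
  }
  counts <- c(n_triads = sum(group_class == "triad"),
              n_duplets = sum(group_class == "duplet"),
              n_monads = sum(gene_class == "monad"),
              n_ug = sum(is_ug))
  list(gene_class = gene_class, group_class = group_class, counts = counts)
}

#' Subgenome gene counts and percentages for the whole genome
#'
#' @param table a [homology_table()].
#' @return data.frame with one row per subgenome (LF, MF1, MF2, UG):
#'   `count`, `fraction` (exact) and `percent` (one decimal, rounded half
#'   away from zero, as printed figures report them).
#' @export
genome_composition <- function(table) {
  stopifnot(inherits(table, "homology_table"))
  if (nrow(table) == 0) stop("genome_composition: empty homology table")
  levels <- c(.SUBGENOMES, "UG")
  count <- as.integer(table(factor(table$subgenome, levels = levels)))
  frac <- count / sum(count)
  data.frame(subgenome = levels, count = count, fraction = frac,
             percent = round_half_up(100 * frac, 1))
}

#' Per-cluster subgenome shares of expressed genes
#'
#' For each cluster, the proportion of expressed genes that belong to each
#' subgenome, among all expressed genes of that cluster.
#'
#' @param profile a [pseudobulk()] profile with `expressed` set.
#' @param table a [homology_table()].
#' @return data.frame: cluster, subgenome, n_expressed, proportion.
#' @export
expressed_composition <- function(profile, table) {
  stopifnot(inherits(profile, "cluster_profile"),
            inherits(table, "homology_table"))
  if (is.null(profile$expressed))
    stop("expressed_composition: profile has no expressed matrix")
  sg <- stats::setNames(table$subgenome, table$gene_id)
  genes <- colnames(profile$expressed)
  gsg <- factor(sg[genes], levels = c(.SUBGENOMES, "UG"))
  out <- do.call(rbind, lapply(profile$clusters, function(cl) {
    expr <- profile$expressed[cl, ]
    n_tot <- sum(expr)
    if (n_tot == 0) stop("expressed_composition: cluster ", cl,
                         " has no expressed genes")
    n <- tapply(expr, gsg, sum, default = 0L)
    data.frame(cluster = cl, subgenome = names(n),
               n_expressed = as.integer(n), proportion = as.numeric(n) / n_tot)
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of gene expression across subgenomes in one cluster
#'
#' The unit of observation is a gene: each expressed gene contributes its
#' mean normalized expression in the cluster, and expression is compared
#' across the subgenome groups (LF, MF1, MF2, UG) by fixed-effects one-way
#' ANOVA. Alongside the omnibus F test, the three contrasts a composition
#' figure typically annotates (each of LF/MF1/MF2 against UG) are reported
#' as pooled-variance t tests on the ANOVA residual variance.
#'
#' @param profile a [pseudobulk()] profile with `expressed` set.
#' @param table a [homology_table()].
#' @param cluster cluster label to analyse.
#' @return list with `F`, `p`, `df`, `group_means`, `group_n` and
#'   `contrasts` (data.frame of LF/MF1/MF2 vs UG estimates and p-values;
#'   NULL when UG has fewer than 2 expressed genes).
#' @export
subgenome_anova <- function(profile, table, cluster) {
  stopifnot(inherits(profile, "cluster_profile"),
            inherits(table, "homology_table"))
  if (!cluster %in% profile$clusters)
    stop("subgenome_anova: unknown cluster ", cluster)
  if (is.null(profile$expressed))
    stop("subgenome_anova: profile has no expressed matrix")
  sg <- stats::setNames(table$subgenome, table$gene_id)
  genes <- colnames(profile$mean_expr)
  keep <- profile$expressed[cluster, ] & !is.na(sg[genes])
  y <- profile$mean_expr[cluster, keep]
  g <- factor(sg[genes[keep]], levels = c(.SUBGENOMES, "UG"))
  g <- droplevels(g)
  n <- table(g)
  if (length(n) < 2 || any(n < 2)) {
    small <- if (length(n) < 2) "fewer than 2 groups" else
      paste("group", names(n)[n < 2][1], "has <2 expressed genes")
    stop("subgenome_anova: insufficient data in cluster ", cluster,
         " (", small, ")")
  }
  fit <- stats::lm(y ~ g)
  # degenerate inputs (perfect fit) warn inside anova.lm; handled below
  av <- suppressWarnings(stats::anova(fit))
  means <- tapply(y, g, mean)
  means <- stats::setNames(as.numeric(means), names(means))
  mse <- av["Residuals", "Mean Sq"]
  dfr <- av["Residuals", "Df"]
  contrasts <- NULL
  if ("UG" %in% levels(g) && n[["UG"]] >= 2) {
    others <- setdiff(levels(g), "UG")
    est <- means[others] - means[["UG"]]
    se <- sqrt(mse * (1 / n[others] + 1 / n[["UG"]]))
    tval <- est / se
    contrasts <- data.frame(
      contrast = paste0(others, "-UG"), estimate = as.numeric(est),
      t = as.numeric(tval),
      p = 2 * stats::pt(abs(tval), dfr, lower.tail = FALSE),
      row.names = NULL)
  }
  Fv <- av["g", "F value"]
  pv <- av["g", "Pr(>F)"]
  # constant response: zero between and within SS; define F = 0, p = 1
  if (all(abs(y - y[1]) < 1e-12) || is.nan(Fv)) {
    Fv <- 0; pv <- 1
  }
  list(F = Fv, p = pv, df = c(av["g", "Df"], dfr),
       group_means = means, group_n = as.integer(n), contrasts = contrasts)
}

#' Fraction of each homoeolog-group class expressed per cluster
#'
#' For each cluster and each class (triad, duplet, monad, ungrouped), the
#' fraction of the class's genes called expressed in that cluster. A class
#' with zero genes in the genome yields NA rather than an error.
#'
#' @param profile a [pseudobulk()] profile with `expressed` set.
#' @param table a [homology_table()].
#' @param classes optional precomputed [classify_groups()] result.
#' @return data.frame: cluster, class, n_genes, n_expressed, fraction.
#' @export
expressed_fraction_by_class <- function(profile, table, classes = NULL) {
  stopifnot(inherits(profile, "cluster_profile"),
            inherits(table, "homology_table"))
  if (is.null(profile$expressed))
    stop("expressed_fraction_by_class: profile has no expressed matrix")
  if (is.null(classes)) classes <- classify_groups(table)
  lev <- c("triad", "duplet", "monad", "ungrouped")
  genes <- colnames(profile$expressed)
  gcl <- factor(classes$gene_class[genes], levels = lev)
  n_genes <- table(gcl)
  out <- do.call(rbind, lapply(profile$clusters, function(cl) {
    n_expr <- tapply(profile$expressed[cl, ], gcl, sum, default = 0L)
    data.frame(cluster = cl, class = lev, n_genes = as.integer(n_genes),
               n_expressed = as.integer(n_expr),
               fraction = ifelse(n_genes > 0,
                                 as.numeric(n_expr) / as.numeric(n_genes),
                                 NA_real_))
  }))
  rownames(out) <- NULL
  out
}
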