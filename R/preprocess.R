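#' Quality-control thresholds
#'
#' Per-cell and per-gene filters applied before any expression analysis:
#' cells must detect between `min_genes` and `max_genes` genes, carry at most
#' `max_mito_frac` of their counts on mitochondrial genes and at most
#' `max_chloro_frac` on chloroplast genes; genes must then be detected in at
#' least `min_cells_per_gene` of the surviving cells. Organelle gene sets are
#' supplied as explicit id lists (no annotation inference).
#'
#' @param min_genes minimum detected genes per cell (default 200).
#' @param max_genes maximum detected genes per cell (default 11000).
#' @param max_mito_frac maximum mitochondrial count fraction (default 0.05).
#' @param max_chloro_frac maximum chloroplast count fraction (default 0.30).
#' @param min_cells_per_gene minimum cells detecting a gene (default 3).
#' @param mito_genes,chloro_genes character vectors of organelle gene ids.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 11000,
                          max_mito_frac = 0.05, max_chloro_frac = 0.30,
                          min_cells_per_gene = 3,
                          mito_genes = character(),
                          chloro_genes = character()) {
  stopifnot(min_genes < max_genes,
            max_mito_frac >= 0, max_mito_frac <= 1,
            max_chloro_frac >= 0, max_chloro_frac <= 1,
            min_cells_per_gene >= 0)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_frac = max_mito_frac,
                 max_chloro_frac = max_chloro_frac,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_genes = mito_genes, chloro_genes = chloro_genes),
            class = "qc_thresholds")
}

#' Apply quality-control filters
#'
#' Removes cells violating any per-cell rule, then genes detected in fewer
#' than `min_cells_per_gene` of the surviving cells. The per-rule removal
#' tally is attached as attribute `"qc_summary"` and emitted as a message.
#' The operation is idempotent: a matrix that already passes is unchanged.
#'
#' @param cm a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return the filtered [count_matrix()] with attribute `qc_summary`.
#' @export
qc_filter <- function(cm, thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  counts <- cm$counts
  n_genes_cell <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  frac_of <- function(set) {
    idx <- cm$gene_ids %in% set
    if (!any(idx)) return(rep(0, nrow(counts)))
    part <- Matrix::rowSums(counts[, idx, drop = FALSE])
    ifelse(total > 0, part / total, 0)
  }
  mito <- frac_of(thresholds$mito_genes)
  chloro <- frac_of(thresholds$chloro_genes)
  low <- n_genes_cell < thresholds$min_genes
  high <- n_genes_cell > thresholds$max_genes
  mito_bad <- mito > thresholds$max_mito_frac
  chloro_bad <- chloro > thresholds$max_chloro_frac
  keep_cell <- !(low | high | mito_bad | chloro_bad)
  summary <- list(cells_low_genes = sum(low), cells_high_genes = sum(high),
                  cells_high_mito = sum(mito_bad),
                  cells_high_chloro = sum(chloro_bad),
                  cells_removed = sum(!keep_cell))
  if (!any(keep_cell))
    stop("qc_filter: all cells removed (low genes: ", summary$cells_low_genes,
         ", high genes: ", summary$cells_high_genes, ", mito: ",
         summary$cells_high_mito, ", chloro: ", summary$cells_high_chloro, ")")
  sub <- counts[keep_cell, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(sub > 0)
  keep_gene <- cells_per_gene >= thresholds$min_cells_per_gene
  summary$genes_removed <- sum(!keep_gene)
  message("qc_filter: removed ", summary$cells_removed, " cells and ",
          summary$genes_removed, " genes")
  out <- count_matrix(sub[, keep_gene, drop = FALSE],
                      barcodes = cm$barcodes[keep_cell],
                      gene_ids = cm$gene_ids[keep_gene],
                      clusters = cm$clusters[keep_cell])
  attr(out, "qc_summary") <- summary
  out
}

#' Library-size normalization (CP10K + log1p)
#'
#' Each cell's counts are divided by the cell total, multiplied by `scale`
#' (default 1e4) and transformed with log(1 + x). Zero entries stay zero and
#' sparsity is preserved.
#'
#' @param cm a [count_matrix()] (post QC).
#' @param scale scale factor (default 1e4).
#' @return sparse cells x genes matrix of normalized expression.
#' @export
normalize_counts <- function(cm, scale = 1e4) {
  stopifnot(inherits(cm, "count_matrix"), scale > 0)
  total <- Matrix::rowSums(cm$counts)
  if (any(total == 0))
    stop("normalize_counts: ", sum(total == 0),
         " cell(s) with zero total counts; run qc_filter first")
  norm <- Matrix::Diagonal(x = scale / total) %*% cm$counts
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(cm$counts)
  norm
}

.cluster_factor <- function(cm, clusters = NULL) {
  cl <- if (is.null(clusters)) cm$clusters else clusters
  if (is.null(cl)) stop("cluster labels are required (see read_clusters)")
  factor(cl)
}

## sparse cells x clusters indicator (robust to a single cluster level)
.group_indicator <- function(cl) {
  Matrix::sparseMatrix(i = seq_along(cl), j = as.integer(cl), x = 1,
                       dims = c(length(cl), nlevels(cl)))
}

#' Detect genes expressed per cluster
#'
#' A gene is called expressed in a cluster when it has raw count >=
#' `min_count` in at least `min_cells` cells of that cluster. The default
#' (one count in one cell) is the most permissive detection rule; both knobs
#' are monotone — raising either never adds expressed genes.
#'
#' @param cm a [count_matrix()] with cluster labels.
#' @param min_cells minimum qualifying cells (default 1).
#' @param min_count minimum raw count per qualifying cell (default 1).
#' @return logical cluster x gene matrix.
#' @export
detect_expressed <- function(cm, min_cells = 1, min_count = 1) {
  stopifnot(inherits(cm, "count_matrix"), min_cells >= 1, min_count >= 1)
  cl <- .cluster_factor(cm)
  if (any(table(cl) == 0)) stop("detect_expressed: empty cluster")
  det <- cm$counts >= min_count          # logical sparse
  ind <- .group_indicator(cl)            # cells x clusters
  hits <- Matrix::t(ind) %*% det         # clusters x genes cell counts
  out <- as.matrix(hits) >= min_cells
  dimnames(out) <- list(levels(cl), cm$gene_ids)
  out
}

#' Aggregate cells to per-cluster pseudobulk profiles
#'
#' Computes the arithmetic mean of (by default log-normalized) expression
#' over the cells of each cluster, yielding a cluster x gene profile — the
#' substrate for composition statistics and triad bias classification.
#'
#' @param norm cells x genes matrix of normalized expression
#'   (see [normalize_counts()]).
#' @param clusters cluster label per cell (row).
#' @param expressed optional cluster x gene logical matrix from
#'   [detect_expressed()] to carry along.
#' @return a list of class `cluster_profile` with `clusters`, `mean_expr`
#'   (cluster x gene), `expressed` (or NULL) and `n_cells`.
#' @export
pseudobulk <- function(norm, clusters, expressed = NULL) {
  cl <- factor(clusters)
  if (length(cl) != nrow(norm))
    stop("pseudobulk: ", length(cl), " labels for ", nrow(norm), " cells")
  n_cells <- as.integer(table(cl))
  if (any(n_cells == 0)) stop("pseudobulk: empty cluster")
  ind <- .group_indicator(cl)
  sums <- Matrix::t(ind) %*% norm
  mean_expr <- as.matrix(sums) / n_cells
  dimnames(mean_expr) <- list(levels(cl), colnames(norm))
  if (!is.null(expressed)) {
    stopifnot(identical(rownames(expressed), levels(cl)),
              identical(colnames(expressed), colnames(norm)))
  }
  structure(list(clusters = levels(cl), mean_expr = mean_expr,
                 expressed = expressed,
                 n_cells = stats::setNames(n_cells, levels(cl))),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("cluster_profile: ", length(x$clusters), " clusters x ",
      ncol(x$mean_expr), " genes (", sum(x$n_cells), " cells)\n", sep = "")
  invisible(x)
}

#' Write a cluster profile as a long TSV
#'
#' Columns: cluster, gene, mean_expr, expressed (if available).
#' @param profile a [pseudobulk()] profile.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cluster_profile"))
  long <- data.frame(
    cluster = rep(profile$clusters, times = ncol(profile$mean_expr)),
    gene = rep(colnames(profile$mean_expr), each = length(profile$clusters)),
    mean_expr = as.vector(profile$mean_expr))
  if (!is.null(profile$expressed))
    long$expressed <- as.vector(profile$expressed)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
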