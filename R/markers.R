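#' Marker detection settings
#'
#' Cluster-enriched genes are called with a one-directional gate: a gene
#' must be detected in at least `min_pct` of cells (by default in either the
#' cluster or the rest — `pct_mode = "max"`; set `"in"` to gate on the
#' cluster only) and show log2 fold-change of at least `logfc_threshold`
#' (0.58 ~ log2(1.5)) of in-cluster over out-of-cluster mean normalized
#' expression, with `pseudocount` added to both means, before the rank-sum
#' test is run.
#'
#' @param logfc_threshold minimum log2 fold-change (default 0.58).
#' @param min_pct minimum detection fraction (default 0.25).
#' @param alpha FDR level used by callers to threshold q-values
#'   (default 0.05).
#' @param pseudocount added to both means before the fold-change log
#'   (default 1).
#' @param pct_mode `"max"` (default) or `"in"`; which detection fraction the
#'   `min_pct` gate applies to.
#' @return a list of class `marker_config`.
#' @export
marker_config <- function(logfc_threshold = 0.58, min_pct = 0.25,
                          alpha = 0.05, pseudocount = 1,
                          pct_mode = c("max", "in")) {
  pct_mode <- match.arg(pct_mode)
  stopifnot(logfc_threshold >= 0 || is.infinite(logfc_threshold),
            min_pct >= 0, min_pct <= 1, pseudocount > 0)
  structure(list(logfc_threshold = logfc_threshold, min_pct = min_pct,
                 alpha = alpha, pseudocount = pseudocount,
                 pct_mode = pct_mode), class = "marker_config")
}

## Two-sided Wilcoxon rank-sum p-values for every column of `mat`, cells in
## `in_idx` vs the rest. Normal approximation with tie correction and
## continuity correction, vectorized over genes (the per-gene exact test is
## needless at matrix scale). Returns data.frame(U, p).
.ranksum_test <- function(mat, in_idx) {
  n1 <- sum(in_idx)
  n2 <- sum(!in_idx)
  N <- n1 + n2
  U <- numeric(ncol(mat))
  sigma <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    rk <- rank(v)
    U[j] <- sum(rk[in_idx]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma[j] <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  }
  mu <- n1 * n2 / 2
  z <- U - mu
  # continuity correction toward the null, as in stats::wilcox.test
  z <- sign(z) * pmax(abs(z) - 0.5, 0)
  p <- ifelse(sigma > 0, 2 * stats::pnorm(abs(z / sigma), lower.tail = FALSE),
              1)
  data.frame(U = U, p = pmin(p, 1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement (wraps
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Find cluster-enriched genes (Wilcoxon rank-sum, cluster vs rest)
#'
#' For each cluster and gene the detection fractions inside and outside the
#' cluster and the log2 fold-change of mean normalized expression are
#' computed; genes failing the `min_pct` or `logfc_threshold` gates are
#' skipped, survivors are tested with the two-sided rank-sum test, and
#' Benjamini-Hochberg adjustment is applied across all tests performed.
#' Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param norm cells x genes normalized expression matrix
#'   (see [normalize_counts()]).
#' @param clusters cluster label per cell.
#' @param config a [marker_config()].
#' @return data.frame: gene, cluster, log2fc, pct_in, pct_out, U, p_value,
#'   q_value, ordered by cluster then p_value.
#' @export
find_markers <- function(norm, clusters, config = marker_config()) {
  stopifnot(inherits(config, "marker_config"))
  cl <- factor(clusters)
  if (length(cl) != nrow(norm))
    stop("find_markers: ", length(cl), " labels for ", nrow(norm), " cells")
  if (nlevels(cl) < 2) stop("find_markers: need at least 2 clusters")
  norm <- as.matrix(norm)
  detected <- norm > 0
  out <- list()
  for (lev in levels(cl)) {
    in_idx <- cl == lev
    if (sum(in_idx) < 3) {
      warning("find_markers: cluster ", lev, " has fewer than 3 cells; ",
              "skipped")
      next
    }
    pct_in <- colMeans(detected[in_idx, , drop = FALSE])
    pct_out <- colMeans(detected[!in_idx, , drop = FALSE])
    mean_in <- colMeans(norm[in_idx, , drop = FALSE])
    mean_out <- colMeans(norm[!in_idx, , drop = FALSE])
    log2fc <- log2((mean_in + config$pseudocount) /
                   (mean_out + config$pseudocount))
    pct_gate <- if (config$pct_mode == "max") pmax(pct_in, pct_out) else
      pct_in
    keep <- pct_gate >= config$min_pct & log2fc >= config$logfc_threshold
    if (!any(keep)) next
    test <- .ranksum_test(norm[, keep, drop = FALSE], in_idx)
    out[[lev]] <- data.frame(
      gene = colnames(norm)[keep], cluster = lev, log2fc = log2fc[keep],
      pct_in = pct_in[keep], pct_out = pct_out[keep], U = test$U,
      p_value = test$p, row.names = NULL)
  }
  if (length(out) == 0)
    return(data.frame(gene = character(), cluster = character(),
                      log2fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), U = numeric(),
                      p_value = numeric(), q_value = numeric()))
  res <- do.call(rbind, out)
  res$q_value <- bh_adjust(res$p_value)
  res <- res[order(res$cluster, res$p_value), ]
  rownames(res) <- NULL
  res
}
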