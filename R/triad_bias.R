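#' The seven homoeolog expression bias categories and their centroids
#'
#' Category centroids live on the 2-simplex of relative contributions
#' (ordered LF, MF1, MF2): the balanced center (1/3,1/3,1/3), the three
#' dominant vertices where one subgenome carries all expression, and the
#' three suppressed edge midpoints where one subgenome is silent and the
#' other two share expression equally. The row order doubles as the
#' deterministic tie-break order (Balanced first).
#'
#' @return 7 x 3 numeric matrix, rownames = category names, colnames =
#'   c("LF","MF1","MF2").
#' @export
bias_centroids <- function() {
  m <- rbind(
    Balanced      = c(1/3, 1/3, 1/3),
    LF_dominant   = c(1,   0,   0),
    MF1_dominant  = c(0,   1,   0),
    MF2_dominant  = c(0,   0,   1),
    LF_suppressed = c(0,   1/2, 1/2),
    MF1_suppressed = c(1/2, 0,   1/2),
    MF2_suppressed = c(1/2, 1/2, 0))
  colnames(m) <- c("LF", "MF1", "MF2")
  m
}

#' Bias classification settings
#'
#' @param min_total_expr minimum summed mean normalized expression of the
#'   three homoeologs for a triad to be classified in a cluster (default
#'   0.5); triads below it are excluded from category proportions.
#' @return a list of class `bias_config`.
#' @export
bias_config <- function(min_total_expr = 0.5) {
  stopifnot(min_total_expr >= 0)
  structure(list(min_total_expr = min_total_expr), class = "bias_config")
}

#' Relative contribution of each homoeolog to triad expression
#'
#' @param e nonnegative expression triple (LF, MF1, MF2) or a matrix with
#'   three columns (one triad per row).
#' @return the triple(s) divided by the row sum; exact simplex membership.
#'   Zero-sum rows are an error — filter before calling.
#' @export
relative_contribution <- function(e) {
  if (is.null(dim(e))) e <- matrix(e, nrow = 1)
  if (ncol(e) != 3) stop("relative_contribution: need 3 columns")
  if (any(e < 0)) stop("relative_contribution: negative expression")
  s <- rowSums(e)
  if (any(s == 0))
    stop("relative_contribution: zero total expression; ",
         "apply the expression filter first")
  r <- e / s
  if (nrow(r) == 1) r <- drop(r)
  r
}

## distances from simplex points (rows of r, n x 3) to the 7 centroids;
## returns n x 7 matrix in centroid order
.centroid_distances <- function(r) {
  C <- bias_centroids()
  d <- sapply(seq_len(nrow(C)), function(k) {
    sqrt((r[, 1] - C[k, 1])^2 + (r[, 2] - C[k, 2])^2 + (r[, 3] - C[k, 3])^2)
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  colnames(d) <- rownames(C)
  d
}

#' Classify a relative-contribution triple by nearest centroid
#'
#' Assigns the bias category whose centroid is closest in plain Euclidean
#' distance on the simplex. Exact ties are broken deterministically in favor
#' of the earlier category in [bias_centroids()] order (Balanced first).
#'
#' @param r simplex triple (LF, MF1, MF2); must sum to 1 within 1e-6.
#' @return list with `category` (character) and `distances` (named
#'   7-vector).
#' @export
classify_triad <- function(r) {
  r <- as.numeric(r)
  if (length(r) != 3 || any(r < -1e-6) || abs(sum(r) - 1) > 1e-6)
    stop("classify_triad: input is not on the simplex")
  d <- .centroid_distances(matrix(r, nrow = 1))[1, ]
  list(category = names(d)[which.min(d)], distances = d)
}

#' Classify every triad in every cluster
#'
#' For each cluster, gathers the mean normalized expression of the three
#' homoeologs of every 1:1:1 triad, filters on total expression, converts
#' survivors to relative contributions and assigns the nearest-centroid bias
#' category. Homoeologs absent from the profile (e.g. removed by gene QC
#' because they are never detected) contribute zero expression.
#'
#' @param profile a [pseudobulk()] profile.
#' @param table a [homology_table()] containing at least one triad.
#' @param config a [bias_config()].
#' @return list with `assignments` (data.frame: triad_id, cluster, the e and
#'   r triples, seven distances, category, passed_filter), `proportions`
#'   (data.frame: cluster, category, n, proportion among assigned triads),
#'   and `unbalanced` (data.frame: cluster, n_assigned, n_filtered,
#'   unbalanced_fraction = 1 - proportion(Balanced)).
#' @export
classify_all <- function(profile, table, config = bias_config()) {
  stopifnot(inherits(profile, "cluster_profile"),
            inherits(table, "homology_table"),
            inherits(config, "bias_config"))
  cls <- classify_groups(table)
  triad_ids <- names(cls$group_class)[cls$group_class == "triad"]
  if (length(triad_ids) == 0) stop("classify_all: no triads in the table")
  tg <- table[table$group_id %in% triad_ids, ]
  # gene of each subgenome per triad, triads in sorted id order
  triad_ids <- sort(triad_ids)
  gene_of <- vapply(.SUBGENOMES, function(s) {
    rows <- tg[tg$subgenome == s, ]
    stats::setNames(rows$gene_id, rows$group_id)[triad_ids]
  }, character(length(triad_ids)))
  gene_of <- matrix(gene_of, ncol = 3,
                    dimnames = list(triad_ids, .SUBGENOMES))
  expr_of <- function(cluster, ids) {
    v <- rep(0, length(ids))
    hit <- ids %in% colnames(profile$mean_expr)
    v[hit] <- profile$mean_expr[cluster, ids[hit]]
    v
  }
  cats <- rownames(bias_centroids())
  res <- lapply(profile$clusters, function(cl) {
    e <- cbind(expr_of(cl, gene_of[, "LF"]), expr_of(cl, gene_of[, "MF1"]),
               expr_of(cl, gene_of[, "MF2"]))
    total <- rowSums(e)
    pass <- total >= config$min_total_expr & total > 0
    r <- matrix(NA_real_, nrow(e), 3)
    d <- matrix(NA_real_, nrow(e), length(cats),
                dimnames = list(NULL, cats))
    category <- rep(NA_character_, nrow(e))
    if (any(pass)) {
      rp <- e[pass, , drop = FALSE] / total[pass]
      r[pass, ] <- rp
      dp <- .centroid_distances(rp)
      d[pass, ] <- dp
      category[pass] <- cats[apply(dp, 1, which.min)]
    }
    data.frame(triad_id = triad_ids, cluster = cl,
               e_LF = e[, 1], e_MF1 = e[, 2], e_MF2 = e[, 3],
               r_LF = r[, 1], r_MF1 = r[, 2], r_MF2 = r[, 3],
               d, category = category, passed_filter = pass,
               row.names = NULL)
  })
  assignments <- do.call(rbind, res)
  props <- do.call(rbind, lapply(profile$clusters, function(cl) {
    sub <- assignments[assignments$cluster == cl & assignments$passed_filter, ]
    if (nrow(sub) == 0)
      return(data.frame(cluster = cl, category = cats, n = 0L,
                        proportion = NA_real_))
    n <- table(factor(sub$category, levels = cats))
    data.frame(cluster = cl, category = cats, n = as.integer(n),
               proportion = as.numeric(n) / nrow(sub))
  }))
  rownames(props) <- NULL
  if (all(is.na(props$proportion)))
    stop("classify_all: no triad passes the expression filter in any cluster")
  unbalanced <- do.call(rbind, lapply(profile$clusters, function(cl) {
    sub <- props[props$cluster == cl, ]
    data.frame(cluster = cl, n_assigned = sum(sub$n),
               n_filtered = length(triad_ids) - sum(sub$n),
               unbalanced_fraction =
                 1 - sub$proportion[sub$category == "Balanced"])
  }))
  rownames(unbalanced) <- NULL
  list(assignments = assignments, proportions = props,
       unbalanced = unbalanced)
}

#' Planar ternary-plot coordinates for simplex points
#'
#' Standard equilateral-triangle embedding with the LF vertex at the origin,
#' MF1 at (1, 0) and MF2 at (1/2, sqrt(3)/2):
#' x = r_MF1 + r_MF2 / 2, y = sqrt(3)/2 * r_MF2.
#'
#' @param r simplex triple (LF, MF1, MF2) or matrix with three columns.
#' @return data.frame with columns `x`, `y`.
#' @export
ternary_coordinates <- function(r) {
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  if (ncol(r) != 3 || any(r < -1e-6) || any(abs(rowSums(r) - 1) > 1e-6))
    stop("ternary_coordinates: input is not on the simplex")
  data.frame(x = r[, 2] + r[, 3] / 2, y = sqrt(3) / 2 * r[, 3])
}
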