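#' Genome partition of the triplicated reference, optionally scaled
#'
#' Returns the published partition of the Chinese cabbage genome into the
#' three subgenomes plus ungrouped genes — LF 16270, MF1 11633, MF2 9653,
#' UG 3464 — together with 2215 homoeologous 1:1:1 triads and 6720 duplets
#' (monads make up the remainder). At `scale < 1` the subgenome sizes, UG,
#' triad and duplet counts are floored and the monad count is re-derived so
#' the partition identity 3*triads + 2*duplets + monads + UG = total genes
#' holds exactly.
#'
#' @param scale multiplicative down-scaling factor in (0, 1].
#' @return list with `subgenome_sizes` (named LF/MF1/MF2/UG), `n_triads`,
#'   `n_duplets`.
#' @export
brapa_genome <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  list(subgenome_sizes = c(LF = floor(16270 * scale),
                           MF1 = floor(11633 * scale),
                           MF2 = floor(9653 * scale),
                           UG = floor(3464 * scale)),
       n_triads = floor(2215 * scale),
       n_duplets = floor(6720 * scale))
}

## published mean per-cluster category proportions; Balanced is the
## complement of the six biased categories
.default_mixture <- c(Balanced = 0.3319, LF_dominant = 0.1646,
                      MF1_dominant = 0.1206, MF2_dominant = 0.1131,
                      LF_suppressed = 0.0724, MF1_suppressed = 0.0933,
                      MF2_suppressed = 0.1041)

#' Simulation configuration
#'
#' Defines a fully self-contained synthetic dataset: a homoeology table
#' whose group sizes follow the (scaled) genome partition, a 12-cluster cell
#' population, and negative-binomial counts in which every triad's
#' per-cluster relative contribution is drawn on the simplex around the
#' centroid of a bias category sampled from `category_mixture`.
#'
#' @param n_clusters number of cell clusters (default 12, labelled V0..).
#' @param cells_per_cluster cells per cluster.
#' @param genome genome partition as returned by [brapa_genome()]; a list
#'   with `subgenome_sizes`, `n_triads`, `n_duplets`.
#' @param category_mixture 7 nonnegative weights over the categories of
#'   [bias_centroids()], summing to 1 (default: the published mean
#'   per-cluster category proportions).
#' @param dominance_strength Dirichlet concentration around the category
#'   centroid; larger is tighter, `Inf` puts every triad exactly on its
#'   centroid.
#' @param nb_mean_log_range range of the per-gene baseline log mean
#'   (natural log of counts per cell at unit size factor).
#' @param nb_dispersion shared NB dispersion (variance = mu + dispersion *
#'   mu^2); 0 gives Poisson counts.
#' @param marker_frac fraction of non-triad genes given a cluster-specific
#'   fold change (triad genes are left untouched so the bias ground truth
#'   stays valid).
#' @param marker_log2fc log2 fold change applied to markers in their home
#'   cluster.
#' @param dropout_extra extra Bernoulli zero-inflation probability.
#' @param mixture_sampling how per-(triad, cluster) categories realize the
#'   mixture: `"quota"` (default) fixes each cluster's category counts to
#'   the largest-remainder apportionment of the mixture and shuffles the
#'   assignment across triads, so the ground truth composition equals the
#'   configured mixture up to rounding; `"multinomial"` draws i.i.d.
#' @param libsize_sigma sdlog of the per-cell lognormal size factor
#'   (meanlog set so E\[size factor\] = 1).
#' @param seed RNG seed; identical configs give byte-identical outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 12, cells_per_cluster = 100,
                       genome = brapa_genome(1),
                       category_mixture = .default_mixture,
                       dominance_strength = 200,
                       nb_mean_log_range = c(log(0.05), log(5)),
                       nb_dispersion = 0.1,
                       marker_frac = 0.1, marker_log2fc = 2,
                       dropout_extra = 0, libsize_sigma = 0.3,
                       mixture_sampling = c("quota", "multinomial"),
                       seed = 1) {
  mixture_sampling <- match.arg(mixture_sampling)
  stopifnot(n_clusters >= 1, cells_per_cluster >= 1,
            all(category_mixture >= 0),
            dominance_strength >= 0,
            length(nb_mean_log_range) == 2,
            nb_mean_log_range[1] <= nb_mean_log_range[2],
            nb_dispersion >= 0, marker_frac >= 0, marker_frac <= 1,
            marker_log2fc >= 0, dropout_extra >= 0, dropout_extra <= 1,
            libsize_sigma >= 0)
  if (abs(sum(category_mixture) - 1) > 1e-9)
    stop("sim_config: category_mixture must sum to 1")
  cats <- rownames(bias_centroids())
  if (is.null(names(category_mixture))) names(category_mixture) <- cats
  if (!identical(sort(names(category_mixture)), sort(cats)))
    stop("sim_config: category_mixture must be named by the 7 categories")
  sizes <- genome$subgenome_sizes
  if (!identical(sort(names(sizes)), sort(c(.SUBGENOMES, "UG"))))
    stop("sim_config: subgenome_sizes must be named LF, MF1, MF2, UG")
  if (any(sizes < 0) || genome$n_triads < 0 || genome$n_duplets < 0)
    stop("sim_config: negative genome counts")
  alloc <- .allocate_groups(sizes, genome$n_triads, genome$n_duplets)
  total <- sum(sizes)
  if (total == 0) stop("sim_config: zero genes")
  structure(list(
    n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
    subgenome_sizes = sizes, n_triads = genome$n_triads,
    n_duplets = genome$n_duplets, n_monads = alloc$n_monads,
    alloc = alloc, category_mixture = category_mixture[cats],
    dominance_strength = dominance_strength,
    nb_mean_log_range = nb_mean_log_range, nb_dispersion = nb_dispersion,
    marker_frac = marker_frac, marker_log2fc = marker_log2fc,
    dropout_extra = dropout_extra, libsize_sigma = libsize_sigma,
    mixture_sampling = mixture_sampling,
    seed = as.integer(seed)), class = "sim_config")
}

## Allocate duplet pair types and per-subgenome monads consistently with the
## subgenome sizes: triads take one gene per subgenome, duplets are split as
## evenly as possible over the three subgenome pairs, monads absorb the rest.
.allocate_groups <- function(sizes, n_triads, n_duplets) {
  rem <- sizes[.SUBGENOMES] - n_triads
  if (any(rem < 0))
    stop("sim_config: subgenome sizes too small for ", n_triads, " triads")
  base <- n_duplets %/% 3
  extra <- n_duplets %% 3
  pair_n <- base + (seq_len(3) <= extra)   # LF:MF1, LF:MF2, MF1:MF2
  names(pair_n) <- c("LF.MF1", "LF.MF2", "MF1.MF2")
  touches <- c(LF = pair_n[["LF.MF1"]] + pair_n[["LF.MF2"]],
               MF1 = pair_n[["LF.MF1"]] + pair_n[["MF1.MF2"]],
               MF2 = pair_n[["LF.MF2"]] + pair_n[["MF1.MF2"]])
  monads <- rem - touches
  if (any(monads < 0))
    stop("sim_config: subgenome sizes inconsistent with the requested ",
         "triad/duplet counts (negative monads for ",
         paste(names(monads)[monads < 0], collapse = ", "), ")")
  list(pair_n = pair_n, monads_per_subgenome = monads,
       n_monads = sum(monads))
}

## Build the homoeology table implied by the allocation; deterministic.
.build_homology <- function(config) {
  a <- config$alloc
  rows <- list()
  tid <- sprintf("triad_%05d", seq_len(config$n_triads))
  for (s in .SUBGENOMES)
    rows[[paste0("tri_", s)]] <- data.frame(
      gene_id = sprintf("%s_t%05d", s, seq_len(config$n_triads)),
      subgenome = s, group_id = tid)
  pairs <- list(LF.MF1 = c("LF", "MF1"), LF.MF2 = c("LF", "MF2"),
                MF1.MF2 = c("MF1", "MF2"))
  offset <- 0
  for (p in names(pairs)) {
    n <- a$pair_n[[p]]
    if (n == 0) next
    did <- sprintf("duplet_%05d", offset + seq_len(n))
    for (s in pairs[[p]])
      rows[[paste0("dup_", p, s)]] <- data.frame(
        gene_id = sprintf("%s_d%05d", s, offset + seq_len(n)),
        subgenome = s, group_id = did)
    offset <- offset + n
  }
  moff <- 0
  for (s in .SUBGENOMES) {
    n <- a$monads_per_subgenome[[s]]
    if (n == 0) next
    rows[[paste0("mon_", s)]] <- data.frame(
      gene_id = sprintf("%s_m%05d", s, moff + seq_len(n)),
      subgenome = s, group_id = sprintf("monad_%05d", moff + seq_len(n)))
    moff <- moff + n
  }
  n_ug <- config$subgenome_sizes[["UG"]]
  if (n_ug > 0)
    rows[["ug"]] <- data.frame(gene_id = sprintf("UG_g%05d", seq_len(n_ug)),
                               subgenome = "UG", group_id = "")
  homology_table(do.call(rbind, rows))
}

## n draws from Dirichlet(alpha); alpha built from a centroid floored at
## 1e-3 so zero components stay samplable, scaled to `strength`.
.rdirichlet_centroid <- function(n, centroid, strength) {
  if (is.infinite(strength))
    return(matrix(centroid, n, 3, byrow = TRUE))
  mu <- pmax(centroid, 1e-3)
  mu <- mu / sum(mu)
  alpha <- strength * mu
  g <- matrix(stats::rgamma(n * 3, shape = rep(alpha, each = n)), n, 3)
  g / rowSums(g)
}

#' Simulate a full dataset with known bias ground truth
#'
#' Builds the homoeology table from the configured genome partition, samples
#' a bias category for every (triad, cluster) pair from the category
#' mixture, draws the triad's relative-contribution triple on the simplex
#' around that category's centroid (Dirichlet, concentration =
#' `dominance_strength`), assigns per-gene per-cluster negative-binomial
#' means (triad homoeologs split the triad's total by the drawn triple;
#' other genes get a baseline mean, markers a fold change in their home
#' cluster), and draws per-cell counts with lognormal size factors and
#' optional zero inflation. Identical configs produce byte-identical
#' outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`, `homology.tsv`, `clusters.tsv` and
#'   `truth.json`.
#' @return (invisibly when writing) a list with `counts` (a
#'   [count_matrix()] with cluster labels), `homology`, `truth` (list:
#'   `categories` data.frame with triad_id, cluster, category and the drawn
#'   r triple; `markers` data.frame; `gene_means` genes x clusters matrix of
#'   configured NB means) and `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  homology <- .build_homology(config)
  genes <- homology$gene_id
  n_genes <- length(genes)
  clusters <- sprintf("V%d", seq_len(config$n_clusters) - 1)
  cats <- rownames(bias_centroids())
  centroids <- bias_centroids()

  # baseline per-gene mean
  base_mean <- exp(stats::runif(n_genes, config$nb_mean_log_range[1],
                                config$nb_mean_log_range[2]))
  names(base_mean) <- genes

  is_triad_gene <- grepl("_t\\d+$", genes)
  triad_ids <- sprintf("triad_%05d", seq_len(config$n_triads))

  # markers among non-triad genes
  non_triad <- genes[!is_triad_gene]
  n_mark <- round(config$marker_frac * length(non_triad))
  marker_genes <- if (n_mark > 0) sample(non_triad, n_mark) else character(0)
  marker_home <- if (n_mark > 0)
    sample(clusters, n_mark, replace = TRUE) else character(0)
  markers <- data.frame(gene = marker_genes, cluster = marker_home)

  # per-(triad, cluster) category and simplex point
  truth_cat <- NULL
  gene_means <- matrix(base_mean, n_genes, config$n_clusters,
                       dimnames = list(genes, clusters))
  if (config$n_triads > 0) {
    triad_total <- 3 * exp(stats::runif(config$n_triads,
                                        config$nb_mean_log_range[1],
                                        config$nb_mean_log_range[2]))
    draw_cluster <- function() {
      if (config$mixture_sampling == "multinomial")
        return(sample(cats, config$n_triads, replace = TRUE,
                      prob = config$category_mixture))
      # largest-remainder apportionment of the mixture, then shuffle
      target <- config$n_triads * config$category_mixture
      n_cat <- floor(target)
      short <- config$n_triads - sum(n_cat)
      if (short > 0) {
        top <- order(target - n_cat, decreasing = TRUE)[seq_len(short)]
        n_cat[top] <- n_cat[top] + 1
      }
      sample(rep(cats, times = n_cat))
    }
    cat_draw <- vapply(seq_len(config$n_clusters), function(k) draw_cluster(),
                       character(config$n_triads))
    cat_draw <- matrix(cat_draw, config$n_triads, config$n_clusters)
    r_all <- array(NA_real_, c(config$n_triads, config$n_clusters, 3))
    for (k in seq_len(config$n_clusters)) {
      for (cat in cats) {
        idx <- which(cat_draw[, k] == cat)
        if (!length(idx)) next
        r_all[idx, k, ] <- .rdirichlet_centroid(length(idx),
                                                centroids[cat, ],
                                                config$dominance_strength)
      }
      for (i in seq_len(3)) {
        gene_means[sprintf("%s_t%05d", .SUBGENOMES[i],
                           seq_len(config$n_triads)), k] <-
          triad_total * r_all[, k, i]
      }
    }
    truth_cat <- data.frame(
      triad_id = rep(triad_ids, times = config$n_clusters),
      cluster = rep(clusters, each = config$n_triads),
      category = as.vector(cat_draw),
      r_LF = as.vector(r_all[, , 1]), r_MF1 = as.vector(r_all[, , 2]),
      r_MF2 = as.vector(r_all[, , 3]))
  }
  if (n_mark > 0) {
    fold <- 2^config$marker_log2fc
    for (i in seq_len(n_mark))
      gene_means[marker_genes[i], marker_home[i]] <-
        gene_means[marker_genes[i], marker_home[i]] * fold
  }

  # counts, cluster by cluster
  n_cells <- config$n_clusters * config$cells_per_cluster
  barcodes <- sprintf("cell_%06d", seq_len(n_cells))
  cell_cluster <- rep(clusters, each = config$cells_per_cluster)
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  blocks <- vector("list", config$n_clusters)
  for (k in seq_len(config$n_clusters)) {
    sf <- stats::rlnorm(config$cells_per_cluster,
                        meanlog = -config$libsize_sigma^2 / 2,
                        sdlog = config$libsize_sigma)
    mu <- outer(gene_means[, k], sf)          # genes x cells
    counts <- if (is.finite(size))
      stats::rnbinom(length(mu), mu = mu, size = size)
    else stats::rpois(length(mu), mu)
    if (config$dropout_extra > 0)
      counts <- counts *
        stats::rbinom(length(counts), 1, 1 - config$dropout_extra)
    blocks[[k]] <- Matrix::Matrix(matrix(counts, nrow = n_genes),
                                  sparse = TRUE)
  }
  counts <- Matrix::t(do.call(cbind, blocks))   # cells x genes
  cm <- count_matrix(counts, barcodes = barcodes, gene_ids = genes,
                     clusters = cell_cluster)
  truth <- list(categories = truth_cat, markers = markers,
                gene_means = gene_means)
  result <- list(counts = cm, homology = homology, truth = truth,
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_10x(cm, out_dir)
    write_homology(homology, file.path(out_dir, "homology.tsv"))
    write_clusters(cm, file.path(out_dir, "clusters.tsv"))
    jsonlite::write_json(
      list(categories = truth_cat, markers = markers,
           seed = config$seed),
      file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
    return(invisible(result))
  }
  result
}
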