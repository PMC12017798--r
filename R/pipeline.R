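#' Pipeline configuration
#'
#' Bundles the input paths and stage settings of the end-to-end analysis.
#'
#' @param counts_dir directory with the 10x-style triplet.
#' @param clusters_tsv per-cell cluster assignment TSV.
#' @param homology_tsv gene homoeology TSV.
#' @param out_dir output directory.
#' @param qc a [qc_thresholds()] (NULL skips QC).
#' @param bias a [bias_config()].
#' @param markers a [marker_config()] (NULL skips marker detection).
#' @param normalize_scale scale factor for [normalize_counts()].
#' @param min_cells_expressed,min_count_expressed detection rule for
#'   [detect_expressed()].
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_dir, clusters_tsv, homology_tsv, out_dir,
                            qc = qc_thresholds(), bias = bias_config(),
                            markers = marker_config(),
                            normalize_scale = 1e4,
                            min_cells_expressed = 1,
                            min_count_expressed = 1, seed = 1) {
  structure(list(counts_dir = counts_dir, clusters_tsv = clusters_tsv,
                 homology_tsv = homology_tsv, out_dir = out_dir, qc = qc,
                 bias = bias, markers = markers,
                 normalize_scale = normalize_scale,
                 min_cells_expressed = min_cells_expressed,
                 min_count_expressed = min_count_expressed,
                 seed = as.integer(seed)), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' QC filter, normalization, expressed-gene detection, pseudobulk
#' aggregation, subgenome composition statistics and ANOVA, triad bias
#' classification and (optionally) marker detection, with every stage table
#' written under `out_dir` plus a JSON manifest of input checksums, the
#' resolved configuration and per-stage row counts. Reruns on identical
#' inputs produce identical outputs. Stage errors are propagated with the
#' stage name attached and inputs are checked up front so failures leave no
#' partial output.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$counts_dir, config$clusters_tsv, config$homology_tsv))
    if (!file.exists(p)) stop("run_pipeline: missing input: ", p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("run_pipeline [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  cm <- stage("read_10x", read_10x(config$counts_dir))
  cm <- stage("read_clusters", read_clusters(config$clusters_tsv, cm))
  homology <- stage("read_homology", read_homology(config$homology_tsv))
  if (!is.null(config$qc)) cm <- stage("qc_filter", qc_filter(cm, config$qc))
  norm <- stage("normalize",
                normalize_counts(cm, scale = config$normalize_scale))
  expressed <- stage("detect_expressed",
                     detect_expressed(cm, config$min_cells_expressed,
                                      config$min_count_expressed))
  profile <- stage("pseudobulk", pseudobulk(norm, cm$clusters, expressed))
  composition <- stage("genome_composition", genome_composition(homology))
  classes <- stage("classify_groups", classify_groups(homology))
  expr_comp <- stage("expressed_composition",
                     expressed_composition(profile, homology))
  class_frac <- stage("expressed_fraction_by_class",
                      expressed_fraction_by_class(profile, homology, classes))
  anova <- stage("subgenome_anova", do.call(rbind, lapply(
    profile$clusters, function(cl) {
      a <- subgenome_anova(profile, homology, cl)
      data.frame(cluster = cl, F = a$F, p = a$p,
                 t(stats::setNames(a$group_means,
                                   paste0("mean_", names(a$group_means)))))
    })))
  bias <- stage("classify_all",
                classify_all(profile, homology, config$bias))
  category_means <- stage("summarize_categories",
                          summarize_categories(bias$proportions))
  marker_tab <- NULL
  if (!is.null(config$markers))
    marker_tab <- stage("find_markers",
                        find_markers(norm, cm$clusters, config$markers))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  files <- c(
    .write_tsv(composition, out("genome_composition.tsv")),
    .write_tsv(expr_comp, out("expressed_composition.tsv")),
    .write_tsv(class_frac, out("class_fractions.tsv")),
    .write_tsv(anova, out("anova.tsv")),
    .write_tsv(bias$assignments, out("assignments.tsv")),
    .write_tsv(bias$proportions, out("category_proportions.tsv")),
    .write_tsv(bias$unbalanced, out("unbalanced.tsv")),
    .write_tsv(category_means, out("category_means.tsv")))
  r_ok <- bias$assignments$passed_filter
  tern <- cbind(ternary_coordinates(as.matrix(
    bias$assignments[r_ok, c("r_LF", "r_MF1", "r_MF2")])),
    category = bias$assignments$category[r_ok],
    cluster = bias$assignments$cluster[r_ok])
  files <- c(files, .write_tsv(tern, out("ternary.tsv")))
  if (!is.null(marker_tab))
    files <- c(files, .write_tsv(marker_tab, out("markers.tsv")))

  manifest <- list(
    seed = config$seed,
    inputs = as.list(tools::md5sum(c(
      matrix.mtx = .find_file(config$counts_dir, "matrix.mtx"),
      clusters = config$clusters_tsv, homology = config$homology_tsv))),
    config = list(normalize_scale = config$normalize_scale,
                  min_cells_expressed = config$min_cells_expressed,
                  min_count_expressed = config$min_count_expressed,
                  qc = unclass(config$qc), bias = unclass(config$bias),
                  markers = unclass(config$markers)),
    stage_rows = list(cells = length(cm$barcodes),
                      genes = length(cm$gene_ids),
                      clusters = length(profile$clusters),
                      triads = unname(classes$counts["n_triads"]),
                      assignments = nrow(bias$assignments),
                      markers = if (is.null(marker_tab)) 0L
                                else nrow(marker_tab)),
    outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(list(counts = cm, normalized = norm, profile = profile,
                 homology = homology, composition = composition,
                 classes = classes, expressed_composition = expr_comp,
                 class_fractions = class_frac, anova = anova, bias = bias,
                 category_means = category_means, markers = marker_tab,
                 manifest = manifest))
}

#' Mean category proportions across clusters
#'
#' Unweighted mean over clusters of each bias category's per-cluster
#' proportion, with the categories ranked by mean proportion — the summary a
#' per-cluster stacked-bar figure is read off as.
#'
#' @param proportions the `proportions` data.frame from [classify_all()].
#' @return data.frame: category, mean_proportion, rank (1 = largest),
#'   ordered by category enum order.
#' @export
summarize_categories <- function(proportions) {
  stopifnot(all(c("cluster", "category", "proportion") %in%
                  names(proportions)))
  cats <- rownames(bias_centroids())
  keep <- !is.na(proportions$proportion)
  if (!any(keep)) stop("summarize_categories: no assigned triads")
  m <- tapply(proportions$proportion[keep],
              factor(proportions$category[keep], levels = cats), mean)
  m[is.na(m)] <- 0
  data.frame(category = cats, mean_proportion = as.numeric(m),
             rank = rank(-as.numeric(m), ties.method = "min"))
}
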