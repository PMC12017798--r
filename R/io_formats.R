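#' Construct a cell x gene count matrix container
#'
#' Light S3 container around a sparse cell x gene matrix of raw UMI counts,
#' the cell barcodes (rows), gene identifiers (columns) and, optionally, a
#' per-cell cluster label. In-memory orientation is always cells x genes;
#' on-disk Matrix Market files follow the 10x convention (genes as rows).
#'
#' @param counts sparse (or dense) nonnegative integer matrix, cells x genes.
#' @param barcodes character vector of unique cell barcodes, one per row.
#' @param gene_ids character vector of unique gene ids, one per column.
#' @param clusters optional character vector of cluster labels, parallel to
#'   `barcodes` (or a named vector keyed by barcode).
#' @return an object of class `count_matrix` with elements `counts`,
#'   `barcodes`, `gene_ids`, `clusters`.
#' @export
count_matrix <- function(counts, barcodes, gene_ids, clusters = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(barcodes))
    stop("count_matrix: ", nrow(counts), " rows but ", length(barcodes),
         " barcodes")
  if (ncol(counts) != length(gene_ids))
    stop("count_matrix: ", ncol(counts), " columns but ", length(gene_ids),
         " gene ids")
  if (anyDuplicated(barcodes)) stop("count_matrix: duplicated barcodes")
  if (anyDuplicated(gene_ids)) stop("count_matrix: duplicated gene ids")
  if (length(counts@x) && min(counts@x) < 0)
    stop("count_matrix: negative counts")
  if (length(counts@x) && any(counts@x != round(counts@x)))
    stop("count_matrix: non-integer counts")
  dimnames(counts) <- list(barcodes, gene_ids)
  if (!is.null(clusters)) {
    if (!is.null(names(clusters))) {
      missing <- setdiff(barcodes, names(clusters))
      if (length(missing))
        stop("count_matrix: no cluster label for ", length(missing),
             " barcodes")
      clusters <- unname(clusters[barcodes])
    }
    if (length(clusters) != length(barcodes))
      stop("count_matrix: cluster labels do not match barcodes")
    clusters <- as.character(clusters)
  }
  structure(list(counts = counts, barcodes = as.character(barcodes),
                 gene_ids = as.character(gene_ids), clusters = clusters),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", length(x$barcodes), " cells x ", length(x$gene_ids),
      " genes, ", length(x$counts@x), " non-zero entries",
      if (!is.null(x$clusters))
        paste0(", ", length(unique(x$clusters)), " clusters"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

## open a possibly gzipped path; returns the first existing candidate
.find_file <- function(dir, base) {
  for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  stop("missing input file: ", file.path(dir, base), "[.gz]")
}

.read_tsv_column <- function(path, col = 1L) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  as.character(tab[[col]])
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally
#' gzipped). The on-disk matrix is genes x cells per the 10x convention and is
#' transposed to the in-memory cells x genes orientation. Feature and barcode
#' files are headerless by 10x convention; set `header = TRUE` if they carry
#' a header line.
#'
#' @param dir directory containing the three files.
#' @param header logical; whether features.tsv/barcodes.tsv have a header.
#' @return a [count_matrix()].
#' @export
read_10x <- function(dir, header = FALSE) {
  mtx <- Matrix::readMM(.find_file(dir, "matrix.mtx"))
  genes <- .read_tsv_column(.find_file(dir, "features.tsv"))
  cells <- .read_tsv_column(.find_file(dir, "barcodes.tsv"))
  if (header) {
    genes <- genes[-1]
    cells <- cells[-1]
  }
  if (nrow(mtx) != length(genes))
    stop("read_10x: matrix has ", nrow(mtx), " rows but features.tsv lists ",
         length(genes), " genes")
  if (ncol(mtx) != length(cells))
    stop("read_10x: matrix has ", ncol(mtx), " columns but barcodes.tsv ",
         "lists ", length(cells), " cells")
  count_matrix(Matrix::t(mtx), barcodes = cells, gene_ids = genes)
}

#' Write a count matrix as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` (genes x cells), a three-column headerless
#' `features.tsv` (id, id, "Gene Expression") and a headerless
#' `barcodes.tsv`, mirroring Cell Ranger output.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_10x <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(cm$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(cm$gene_ids, cm$gene_ids, "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(cm$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

.SUBGENOMES <- c("LF", "MF1", "MF2")

#' Validate a homoeology table
#'
#' A homoeology table maps every gene to a subgenome label (LF, MF1, MF2 or
#' UG for ungrouped) and an optional homoeolog group id. UG genes must have
#' an empty group id; within one group at most one gene per subgenome (the
#' triplication scheme cannot represent >1:>1 patterns, so such tables are
#' rejected outright).
#'
#' @param df data.frame with columns `gene_id`, `subgenome`, `group_id`.
#' @return the validated data.frame with class `homology_table` prepended.
#' @export
homology_table <- function(df) {
  need <- c("gene_id", "subgenome", "group_id")
  if (!all(need %in% names(df)))
    stop("homology table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$gene_id <- as.character(df$gene_id)
  df$subgenome <- as.character(df$subgenome)
  df$group_id <- as.character(df$group_id)
  df$group_id[is.na(df$group_id)] <- ""
  if (anyDuplicated(df$gene_id))
    stop("homology table: duplicated gene_id: ",
         df$gene_id[anyDuplicated(df$gene_id)])
  bad <- setdiff(unique(df$subgenome), c(.SUBGENOMES, "UG"))
  if (length(bad))
    stop("homology table: unknown subgenome label(s): ",
         paste(bad, collapse = ", "))
  if (any(df$subgenome == "UG" & df$group_id != ""))
    stop("homology table: UG genes must have empty group_id")
  grouped <- df[df$group_id != "", ]
  if (nrow(grouped)) {
    dup <- duplicated(grouped[c("group_id", "subgenome")])
    if (any(dup))
      stop("homology table: group ", grouped$group_id[dup][1],
           " has more than one ", grouped$subgenome[dup][1], " gene")
  }
  class(df) <- c("homology_table", "data.frame")
  df
}

#' Read a homoeology table from TSV
#'
#' @param path tab-delimited file with header columns `gene_id`, `subgenome`,
#'   `group_id` (empty for UG and genes without a group).
#' @return a validated [homology_table()].
#' @export
read_homology <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = character(),
                          colClasses = "character")
  homology_table(df)
}

#' Write a homoeology table to TSV
#' @param table a [homology_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homology <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Attach per-cell cluster labels from a TSV
#'
#' Reads a two-column TSV (header: `barcode`, `cluster_id`) and attaches the
#' labels to a count matrix. Cells absent from the TSV are dropped (with a
#' message giving the count); zero overlap is an error. Cluster labels are
#' opaque strings with no ordinal meaning.
#'
#' @param path cluster assignment TSV.
#' @param cm a [count_matrix()].
#' @return the subset [count_matrix()] with `clusters` populated.
#' @export
read_clusters <- function(path, cm) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", colClasses = "character")
  if (!all(c("barcode", "cluster_id") %in% names(tab)))
    stop("cluster TSV must have columns barcode, cluster_id")
  lab <- stats::setNames(tab$cluster_id, tab$barcode)
  keep <- cm$barcodes %in% names(lab)
  if (!any(keep)) stop("read_clusters: no barcodes overlap the count matrix")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_clusters: dropping ", n_drop,
            " cells without a cluster label")
  count_matrix(cm$counts[keep, , drop = FALSE],
               barcodes = cm$barcodes[keep], gene_ids = cm$gene_ids,
               clusters = unname(lab[cm$barcodes[keep]]))
}

#' Write per-cell cluster labels to TSV
#' @param cm a [count_matrix()] with clusters set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"), !is.null(cm$clusters))
  utils::write.table(
    data.frame(barcode = cm$barcodes, cluster_id = cm$clusters),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
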