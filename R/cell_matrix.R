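#' Gene-by-cell count matrix with per-cell metadata
#'
#' The central container of the package: a sparse gene x cell matrix of
#' non-negative integer counts together with a per-cell metadata table.
#' Metadata columns are \code{cell_id}, \code{cell_type}, \code{subclass}
#' (NA for cells that are not a receiver subclass), \code{survival_class}
#' (\code{"high"}, \code{"low"} or NA), \code{timepoint} and
#' \code{condition}. QC metric columns (\code{nUMI}, \code{nGene},
#' \code{mito_rate}, \code{log10GenesPerUMI}) are added by
#' \code{\link{compute_qc_metrics}}.
#'
#' @param counts a matrix or Matrix of non-negative counts, genes in rows,
#'   cells in columns, with unique dimnames.
#' @param cell_meta optional data.frame of per-cell metadata; must contain a
#'   \code{cell_id} column matching \code{colnames(counts)}. Missing
#'   metadata columns are filled with NA.
#' @return an object of class \code{cell_matrix}.
#' @export
cell_matrix <- function(counts, cell_meta = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell ids in counts")
  if (any(counts@x < 0))
    stop("negative counts are not allowed")

  meta_cols <- c("cell_type", "subclass", "survival_class",
                 "timepoint", "condition")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts),
                            stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta))
    stop("cell_meta must contain a 'cell_id' column")
  if (anyDuplicated(cell_meta$cell_id))
    stop("duplicate cell ids in cell_meta")
  missing_cells <- setdiff(colnames(counts), cell_meta$cell_id)
  if (length(missing_cells))
    stop("cell_meta is missing ", length(missing_cells), " cells (e.g. ",
         missing_cells[1], ")")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), ,
                         drop = FALSE]
  for (col in meta_cols)
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- NA_character_
  rownames(cell_meta) <- cell_meta$cell_id

  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  types <- x$cell_meta$cell_type
  if (!all(is.na(types)))
    cat("  cell types:", paste(sort(unique(stats::na.omit(types))),
                               collapse = ", "), "\n")
  tps <- x$cell_meta$timepoint
  if (!all(is.na(tps)))
    cat("  timepoints:", paste(unique(stats::na.omit(tps)),
                               collapse = ", "), "\n")
  if ("nUMI" %in% names(x$cell_meta))
    cat("  QC metrics computed\n")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell_matrix by gene and/or cell
#'
#' Pure subsetting: surviving counts and metadata rows are untouched.
#'
#' @param m a \code{cell_matrix}.
#' @param genes,cells character vectors or indices; NULL keeps all.
#' @return the subset \code{cell_matrix}.
#' @export
subset_cells <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  counts <- m$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  meta <- m$cell_meta[match(colnames(counts), m$cell_meta$cell_id), ,
                      drop = FALSE]
  out <- m
  out$counts <- counts
  out$cell_meta <- meta
  out
}

#' Receiver/sender group label per cell
#'
#' At \code{"subclass"} granularity a cell's label is its subclass when one
#' is annotated, otherwise its cell type; at \code{"cell_type"} granularity
#' it is always the cell type.
#'
#' @param m a \code{cell_matrix}.
#' @param level \code{"cell_type"} or \code{"subclass"}.
#' @return character vector of labels, one per cell.
#' @export
cell_labels <- function(m, level = c("cell_type", "subclass")) {
  level <- match.arg(level)
  meta <- m$cell_meta
  lab <- as.character(meta$cell_type)
  if (level == "subclass") {
    has_sub <- !is.na(meta$subclass) & nzchar(as.character(meta$subclass))
    lab[has_sub] <- as.character(meta$subclass)[has_sub]
  }
  lab
}

#' Library-size normalized expression (counts-per-10k, log1p)
#'
#' The normalization used for marker scoring and all downstream expression
#' summaries: each cell's counts are scaled to a library size of 10,000 and
#' log1p-transformed. Cells with zero total counts stay all-zero.
#'
#' @param m a \code{cell_matrix}.
#' @return a sparse Matrix of the same shape as \code{m$counts}.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "cell_matrix"))
  totals <- Matrix::colSums(m$counts)
  scale <- ifelse(totals > 0, 1e4 / totals, 0)
  norm <- m$counts %*% Matrix::Diagonal(x = scale)
  dimnames(norm) <- dimnames(m$counts)
  norm@x <- log1p(norm@x)
  norm
}

#' Read a count matrix from disk
#'
#' Supports the 10x-style MTX triplet (\code{matrix.mtx},
#' \code{features.tsv}, \code{barcodes.tsv} in one directory) and dense
#' delimited matrices (genes in rows, header row of cell ids). A sidecar
#' per-cell metadata TSV (\code{cell_meta.tsv} next to the matrix, or given
#' via \code{meta_path}) is joined when present.
#'
#' @param path directory (mtx_triplet) or file (dense_delimited).
#' @param format \code{"mtx_triplet"} or \code{"dense_delimited"}.
#' @param meta_path optional path to a cell metadata TSV with a
#'   \code{cell_id} column.
#' @param sep field separator for the dense format.
#' @return a \code{cell_matrix}.
#' @export
load_counts <- function(path, format = c("mtx_triplet", "dense_delimited"),
                        meta_path = NULL, sep = "\t") {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx_file <- file.path(path, "matrix.mtx")
    feat_file <- file.path(path, "features.tsv")
    bc_file <- file.path(path, "barcodes.tsv")
    for (f in c(mtx_file, feat_file, bc_file))
      if (!file.exists(f)) stop("missing file: ", f)
    counts <- Matrix::readMM(mtx_file)
    features <- utils::read.table(feat_file, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.table(bc_file, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)
    if (nrow(features) != nrow(counts))
      stop("features.tsv has ", nrow(features), " rows but matrix has ",
           nrow(counts), " rows")
    if (nrow(barcodes) != ncol(counts))
      stop("barcodes.tsv has ", nrow(barcodes), " rows but matrix has ",
           ncol(counts), " columns")
    dimnames(counts) <- list(features[[1]], barcodes[[1]])
    if (is.null(meta_path)) {
      candidate <- file.path(path, "cell_meta.tsv")
      if (file.exists(candidate)) meta_path <- candidate
    }
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            row.names = 1, check.names = FALSE,
                            stringsAsFactors = FALSE)
    counts <- as.matrix(df)
    storage.mode(counts) <- "double"
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  }
  cell_matrix(counts, meta)
}

#' Write a cell_matrix as a 10x-style MTX triplet
#'
#' Writes \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv} and
#' \code{cell_meta.tsv} into \code{dir}.
#'
#' @param m a \code{cell_matrix}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_counts <- function(m, dir) {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(m$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
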