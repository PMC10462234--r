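#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the total UMI count (\code{nUMI}), the number
#' of detected genes (\code{nGene}), the mitochondrial read fraction
#' (\code{mito_rate} = mitochondrial counts / nUMI) and the library
#' complexity \code{log10GenesPerUMI} = log10(nGene) / log10(nUMI).
#' Mitochondrial genes are recognised by a case-insensitive name prefix.
#' Cells with nUMI <= 1 get an undefined (NA) log10GenesPerUMI so that any
#' complexity filter removes them.
#'
#' @param m a \code{cell_matrix}.
#' @param mito_prefix gene-name prefix marking mitochondrial genes
#'   (default \code{"mt-"}, matched case-insensitively).
#' @return \code{m} with QC columns added to \code{cell_meta}.
#' @export
compute_qc_metrics <- function(m, mito_prefix = "mt-") {
  stopifnot(inherits(m, "cell_matrix"))
  counts <- m$counts
  numi <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  is_mito <- startsWith(tolower(rownames(counts)), tolower(mito_prefix))
  mito_counts <- if (any(is_mito))
    Matrix::colSums(counts[is_mito, , drop = FALSE]) else rep(0, ncol(counts))
  mito_rate <- ifelse(numi > 0, mito_counts / numi, NA_real_)
  lgpu <- ifelse(numi > 1 & ngene > 0, log10(ngene) / log10(numi), NA_real_)
  m$cell_meta$nUMI <- as.integer(numi)
  m$cell_meta$nGene <- as.integer(ngene)
  m$cell_meta$mito_rate <- mito_rate
  m$cell_meta$log10GenesPerUMI <- lgpu
  m
}

#' QC thresholds
#'
#' Container for the five cell-level QC rules. A cell is removed when
#' nUMI < numi_min or nUMI > numi_max, nGene < ngene_min or
#' nGene > ngene_max, mito_rate > mito_max, or
#' log10GenesPerUMI < lgpu_min. All comparisons are strict, so a cell
#' sitting exactly on a boundary is kept.
#'
#' @param numi_min,numi_max bounds on total UMI per cell.
#' @param ngene_min,ngene_max bounds on detected genes per cell.
#' @param mito_max maximum mitochondrial fraction.
#' @param lgpu_min minimum log10GenesPerUMI.
#' @return a \code{qc_thresholds} object.
#' @export
qc_thresholds <- function(numi_min = 800, numi_max = 30000,
                          ngene_min = 350, ngene_max = 7500,
                          mito_max = 0.20, lgpu_min = 0.8) {
  stopifnot(numi_min < numi_max, ngene_min < ngene_max)
  structure(list(numi_min = numi_min, numi_max = numi_max,
                 ngene_min = ngene_min, ngene_max = ngene_max,
                 mito_max = mito_max, lgpu_min = lgpu_min),
            class = "qc_thresholds")
}

#' Named QC threshold presets
#'
#' Presets for the dataset classes this analysis distinguishes:
#' \code{"whole_retina"} (nUMI 800--30000, nGene 350--7500, mito 20\%,
#' complexity 0.8), \code{"rgc"} (nUMI >= 500, nGene >= 250, no upper
#' bounds), \code{"snrna_sham"} (1000--50000, 500--10000, mito 10\%) and
#' \code{"snrna_onc"} (1000--30000, 500--7000, mito 10\%). Which preset
#' fits a given dataset is the caller's decision.
#'
#' @param name preset name.
#' @return a \code{qc_thresholds} object.
#' @export
qc_preset <- function(name = c("whole_retina", "rgc",
                               "snrna_sham", "snrna_onc")) {
  name <- match.arg(name)
  switch(name,
    whole_retina = qc_thresholds(800, 30000, 350, 7500, 0.20, 0.8),
    rgc          = qc_thresholds(500, Inf, 250, Inf, 0.20, 0.8),
    snrna_sham   = qc_thresholds(1000, 50000, 500, 10000, 0.10, 0.8),
    snrna_onc    = qc_thresholds(1000, 30000, 500, 7000, 0.10, 0.8))
}

#' Filter cells on QC metrics
#'
#' Removes every cell violating any of the five rules in \code{t}
#' (see \code{\link{qc_thresholds}} for boundary semantics). Cells with an
#' undefined metric (NA) are removed. Subsetting only: surviving counts are
#' never altered, and the operation is idempotent.
#'
#' @param m a \code{cell_matrix} with QC metrics computed.
#' @param t a \code{qc_thresholds} object.
#' @return the filtered \code{cell_matrix}.
#' @export
qc_filter <- function(m, t) {
  stopifnot(inherits(m, "cell_matrix"), inherits(t, "qc_thresholds"))
  meta <- m$cell_meta
  if (!all(c("nUMI", "nGene", "mito_rate", "log10GenesPerUMI") %in%
           names(meta)))
    stop("QC metrics not computed; call compute_qc_metrics() first")
  keep <- meta$nUMI >= t$numi_min & meta$nUMI <= t$numi_max &
    meta$nGene >= t$ngene_min & meta$nGene <= t$ngene_max &
    meta$mito_rate <= t$mito_max &
    meta$log10GenesPerUMI >= t$lgpu_min
  keep[is.na(keep)] <- FALSE
  subset_cells(m, cells = which(keep))
}

#' Filter genes on detection breadth
#'
#' Drops genes with nonzero counts in fewer than \code{min_cells} cells.
#'
#' @param m a \code{cell_matrix}.
#' @param min_cells minimum number of cells a gene must be detected in
#'   (default 5).
#' @return the filtered \code{cell_matrix}.
#' @export
gene_filter <- function(m, min_cells = 5) {
  stopifnot(inherits(m, "cell_matrix"))
  n_detected <- Matrix::rowSums(m$counts > 0)
  subset_cells(m, genes = which(n_detected >= min_cells))
}

#' Assign cell types from marker genes
#'
#' Each cell is labelled with the type whose marker genes have the highest
#' mean normalized (counts-per-10k, log1p) expression in that cell. Exact
#' ties break to the lexicographically first type name. The margin between
#' the best and second-best score is recorded per cell.
#'
#' @param m a \code{cell_matrix}.
#' @param markers named list: type name -> character vector of marker genes.
#' @return \code{m} with \code{assigned_type} and \code{assign_margin}
#'   columns added to \code{cell_meta}.
#' @export
assign_cell_types <- function(m, markers) {
  stopifnot(inherits(m, "cell_matrix"))
  if (!length(markers)) stop("markers must be a non-empty named list")
  norm <- normalize_counts(m)
  types <- sort(names(markers))
  scores <- matrix(NA_real_, nrow = ncol(norm), ncol = length(types),
                   dimnames = list(colnames(norm), types))
  for (tp in types) {
    present <- intersect(markers[[tp]], rownames(norm))
    if (!length(present))
      stop("no marker genes of type '", tp, "' are present in the matrix")
    scores[, tp] <- Matrix::colMeans(norm[present, , drop = FALSE])
  }
  # which.max on the lexicographically sorted columns gives the tie-break
  best <- apply(scores, 1L, which.max)
  margin <- if (length(types) > 1) {
    sorted <- apply(scores, 1L, sort, decreasing = TRUE)
    sorted[1, ] - sorted[2, ]
  } else scores[, 1]
  m$cell_meta$assigned_type <- types[best]
  m$cell_meta$assign_margin <- as.numeric(margin)
  m
}

#' Read a marker map from TSV or JSON
#'
#' TSV input needs \code{cell_type} and \code{gene} columns (one marker per
#' row); JSON input is an object mapping type name to gene array.
#'
#' @param path file path (.json parsed as JSON, anything else as TSV).
#' @return named list: type -> character vector of genes.
#' @export
load_markers <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(raw, as.character))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(df)))
    stop("marker TSV needs 'cell_type' and 'gene' columns")
  split(df$gene, df$cell_type)
}

#' Cross-dataset compatibility check
#'
#' Pearson correlation of log-transformed mean expression profiles over the
#' genes shared by two datasets. Each profile is the per-gene mean of
#' counts-per-10k across cells, log1p-transformed. Requires at least 50
#' shared genes.
#'
#' @param a,b two \code{cell_matrix} objects.
#' @param min_shared minimum number of shared genes (default 50).
#' @return the correlation coefficient.
#' @export
dataset_compatibility <- function(a, b, min_shared = 50) {
  stopifnot(inherits(a, "cell_matrix"), inherits(b, "cell_matrix"))
  shared <- intersect(rownames(a$counts), rownames(b$counts))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared genes; need at least ",
         min_shared)
  profile <- function(m) {
    totals <- Matrix::colSums(m$counts)
    scale <- ifelse(totals > 0, 1e4 / totals, 0)
    cp10k <- m$counts %*% Matrix::Diagonal(x = scale)
    rownames(cp10k) <- rownames(m$counts)
    log1p(Matrix::rowMeans(cp10k[shared, , drop = FALSE]))
  }
  stats::cor(profile(a), profile(b), method = "pearson")
}
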