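#' Pipeline configuration
#'
#' A single document (R list, or YAML/JSON file path) naming the inputs
#' and parameters of a full run. Fields: \code{counts} (directory of an
#' MTX triplet, or NULL to simulate), \code{lr_table}, \code{network},
#' \code{markers} (paths; all optional when simulating -- the generator's
#' ground-truth companions are used), \code{qc_preset} (see
#' \code{\link{qc_preset}}), \code{min_cells_per_gene}, scoring /
#' differential / dynamics parameters, and \code{seed}. All thresholds
#' default to the published values (nUMI 800--30000, nGene 350--7500,
#' mito 20\%, complexity 0.8, detection 10\%, score 0.5, cutoffs
#' +/-0.25, fold change 1.2).
#'
#' @param config list or path to a YAML/JSON file.
#' @return normalized config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  defaults <- list(
    counts = NULL, lr_table = NULL, network = NULL, markers = NULL,
    simulate = TRUE, qc_preset = NULL, mito_prefix = "mt-",
    min_cells_per_gene = 5,
    detect_min = 0.10, score_min = 0.5, beta = 0.5, max_path_len = 4,
    cutoff_hi = 0.25, cutoff_lo = -0.25,
    high_subclasses = c("ipRGC", "alphaRGC", "Gpr88RGC"),
    low_subclasses = NULL,
    fc_min = 1.2, pseudocount = 0.05, delta = 0.25, n_groups = 4,
    top_n = 47, seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!is.null(config$counts)) config$simulate <- FALSE
  config
}

# stage wrapper: any error is re-thrown with the stage name attached
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full communication-analysis pipeline
#'
#' Executes qc -> score -> loop adjustment -> filter -> differential ->
#' dynamics -> aggregate on either a loaded dataset or a synthetic atlas,
#' writing every stage artifact as TSV into \code{out_dir} together with
#' a JSON manifest (parameters, seed, per-stage row counts, and md5
#' hashes of all outputs). Identical configs give byte-identical outputs.
#'
#' Pair selection follows the published flow: pairs are filtered at the
#' major-cell-type level (receivers pooled, e.g. all RGC subclasses as
#' one receiver) and the surviving pairs are then scored per subclass for
#' the differential and dynamics stages.
#'
#' @param config see \code{\link{pipeline_config}}.
#' @param out_dir output directory.
#' @return list with the main in-memory results (invisible alongside the
#'   written artifacts): qc'd matrix, filtered score table, subclass
#'   score table, differential records, aggregate list, dynamics calls,
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("retinacomm")) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (config$simulate) {
    atlas <- run_stage("simulate", {
      generate_atlas(synthetic_config(seed = config$seed))
    })
    m <- atlas$matrix
    truth <- atlas$truth
    lr <- lr_database(truth$lr_pairs)
    net <- signaling_graph(truth$network)
    markers <- truth$markers
  } else {
    m <- run_stage("load", load_counts(config$counts))
    if (is.null(config$lr_table))
      stop("configuration error: 'lr_table' is required when loading data")
    lr <- run_stage("load", load_lr_database(config$lr_table))
    net <- if (!is.null(config$network))
      run_stage("load", load_signaling_graph(config$network)) else NULL
    markers <- if (!is.null(config$markers))
      run_stage("load", load_markers(config$markers)) else NULL
  }

  m <- run_stage("qc", {
    m <- compute_qc_metrics(m, config$mito_prefix)
    thr <- if (is.null(config$qc_preset)) NULL
           else qc_preset(config$qc_preset)
    if (!is.null(thr)) m <- qc_filter(m, thr)
    gene_filter(m, config$min_cells_per_gene)
  })
  if (!is.null(markers))
    m <- run_stage("assign", assign_cell_types(m, markers))

  sparams <- scoring_params(config$detect_min, config$score_min,
                            config$beta)
  subclasses_present <- sort(unique(stats::na.omit(m$cell_meta$subclass)))
  high <- intersect(config$high_subclasses, subclasses_present)
  low <- if (is.null(config$low_subclasses))
    setdiff(subclasses_present, high)
  else intersect(config$low_subclasses, subclasses_present)
  dparams <- differential_params(high, low,
                                 config$cutoff_hi, config$cutoff_lo)
  senders <- sort(setdiff(unique(m$cell_meta$cell_type), "RGC"))

  type_table <- run_stage("score", {
    tab <- score_interactions(m, lr, senders = senders,
                              receivers = "RGC",
                              receiver_level = "cell_type",
                              params = sparams)
    if (!is.null(net))
      tab <- add_loop_adjustment(tab, m, lr, net, sparams,
                                 config$max_path_len)
    tab
  })
  kept <- run_stage("filter", filter_pairs(type_table, sparams))

  kept_pairs <- unique(kept[, c("sender", "ligand", "receptor")])
  sub_table <- run_stage("score_subclass", {
    tab <- score_interactions(m, lr, senders = senders,
                              receivers = c(high, low),
                              receiver_level = "subclass",
                              params = sparams)
    key <- paste(tab$sender, tab$ligand, tab$receptor)
    tab[key %in% paste(kept_pairs$sender, kept_pairs$ligand,
                       kept_pairs$receptor), , drop = FALSE]
  })
  attr(sub_table, "timepoints") <- attr(type_table, "timepoints")
  attr(sub_table, "receiver_level") <- "subclass"

  diff_tab <- run_stage("differential",
                        protective_table(sub_table, dparams))
  agg <- run_stage("aggregate",
                   aggregate_nonredundant(diff_tab, config$top_n))

  dyn <- run_stage("dynamics", {
    prot <- diff_tab[diff_tab$call == "protective", , drop = FALSE]
    if (nrow(prot)) {
      calls <- lapply(seq_len(nrow(prot)), function(i)
        preset_induced(sub_table, prot$sender[i], prot$ligand[i],
                       prot$receptor[i], dparams, config$delta,
                       attr(sub_table, "timepoints")[1]))
      do.call(rbind, calls)
    } else data.frame(sender = character(), ligand = character(),
                      receptor = character(), pre_diff = numeric(),
                      post_diff = numeric(), call = character())
  })

  variable <- run_stage("dynamics", {
    if (nrow(kept)) {
      trajs <- score_trajectories(kept)
      data.frame(trajectory = rownames(trajs),
                 variable = variable_interactions(
                   trajs, config$fc_min, config$pseudocount),
                 stringsAsFactors = FALSE)
    } else data.frame(trajectory = character(), variable = logical())
  })

  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(as.data.frame(df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    tsv(type_table, "scores_celltype.tsv"),
    tsv(kept, "scores_filtered.tsv"),
    tsv(sub_table, "scores_subclass.tsv"),
    tsv(diff_tab, "differential.tsv"),
    tsv(agg, "aggregate_nonredundant.tsv"),
    tsv(dyn, "preset_induced.tsv"),
    tsv(variable, "variable_interactions.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("retinacomm")),
    seed = config$seed,
    parameters = config[c("detect_min", "score_min", "beta",
                          "max_path_len", "cutoff_hi", "cutoff_lo",
                          "fc_min", "pseudocount", "delta", "top_n",
                          "min_cells_per_gene")],
    n_cells = ncol(m$counts), n_genes = nrow(m$counts),
    stage_rows = list(scores_celltype = nrow(type_table),
                      scores_filtered = nrow(kept),
                      scores_subclass = nrow(sub_table),
                      differential = nrow(diff_tab),
                      aggregate = nrow(agg),
                      preset_induced = nrow(dyn)),
    file_md5 = as.list(stats::setNames(as.character(tools::md5sum(files)),
                                       basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(matrix = m, scores = kept, subclass_scores = sub_table,
                 differential = diff_tab, aggregate = agg,
                 preset_induced = dyn, variable = variable,
                 truth = truth, manifest = manifest, out_dir = out_dir))
}
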