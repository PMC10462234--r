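#' Configuration for the synthetic multi-cell-type atlas
#'
#' Describes a labelled synthetic dataset with the statistical structure
#' the downstream pipeline assumes: several sender cell types plus a set
#' of receiver (RGC) subclasses partitioned into high- and low-survival
#' groups, four time points (pre-injury "sham" plus post-injury
#' 12h/24h/48h), negative-binomial counts with lognormal library-size
#' variation, marker genes per label, mitochondrial genes with a
#' recognisable prefix, and planted ligand-receptor interactions whose
#' sender-ligand / receiver-receptor expression is boosted toward a
#' chosen survival class, either at all time points ("preset") or only
#' after injury ("induced"). Optionally, planted sender-receiver feedback
#' loops add a back pair plus the receiver-side relay edges to the ground
#' truth network.
#'
#' Counts are NB(mu, size = nb_dispersion) with
#' mu = base_mean * group multiplier * library factor. Generic genes get a
#' lognormal multiplier per major cell type (sdlog 1.25, i.e. strongly type-restricted expression), a small
#' per-subclass jitter (sdlog 0.1) and per-timepoint jitter (sdlog 0.15),
#' so types differ genuinely while subclasses of one type stay similar.
#' Planted-pair and loop genes have a flat baseline so their boost is the
#' only group structure. A small fraction of cells gets an inflated
#' mitochondrial share to exercise the QC filter.
#'
#' @param n_sender_types number of non-receiver cell types.
#' @param receiver_subclasses data.frame with \code{name} and
#'   \code{survival_class} ("high"/"low") columns; both classes must be
#'   non-empty.
#' @param cells_per_type_per_timepoint cells per (label, timepoint)
#'   group; at least 20.
#' @param n_genes gene universe size.
#' @param n_marker_genes_per_type markers per label.
#' @param mito_gene_fraction fraction of genes named with the "mt-"
#'   prefix.
#' @param mito_inflated_fraction fraction of cells with inflated
#'   mitochondrial expression.
#' @param mito_inflation multiplicative mito boost for those cells.
#' @param nb_mean baseline negative-binomial mean per gene.
#' @param nb_dispersion negative-binomial size parameter.
#' @param marker_boost multiplicative marker elevation in the own label.
#' @param planted_pairs data.frame(ligand, receptor, sender,
#'   target_survival_class in \{high, low, both\}, effect_size >= 1,
#'   dynamics in \{preset, induced\}); NULL builds the default panel of 6
#'   high-targeted pairs (3 preset, 3 induced, effect 4) on generic genes.
#' @param planted_loops data.frame(ligand, receptor, back_ligand,
#'   back_receptor, tf) referencing planted forward pairs; NULL builds 2
#'   default loops.
#' @param n_decoy_pairs unplanted ligand-receptor pairs added to the
#'   ground-truth pair table.
#' @param timepoints ordered labels; the first is the pre-injury one.
#' @param seed integer RNG seed.
#' @return a \code{synthetic_config} object (also carries the gene
#'   universe and label sets).
#' @export
synthetic_config <- function(n_sender_types = 6,
                             receiver_subclasses = NULL,
                             cells_per_type_per_timepoint = 60,
                             n_genes = 600,
                             n_marker_genes_per_type = 5,
                             mito_gene_fraction = 0.02,
                             mito_inflated_fraction = 0.05,
                             mito_inflation = 25,
                             nb_mean = 2.5,
                             nb_dispersion = 2,
                             marker_boost = 8,
                             planted_pairs = NULL,
                             planted_loops = NULL,
                             n_decoy_pairs = 50,
                             timepoints = c("sham", "12h", "24h", "48h"),
                             seed = 1L) {
  if (is.null(receiver_subclasses))
    receiver_subclasses <- data.frame(
      name = c("ipRGC", "alphaRGC", "Gpr88RGC",
               "nRGC1", "nRGC2", "nRGC3"),
      survival_class = c("high", "high", "high", "low", "low", "low"),
      stringsAsFactors = FALSE)
  stopifnot(cells_per_type_per_timepoint >= 20,
            n_sender_types >= 1, length(timepoints) >= 2,
            nb_mean > 0, nb_dispersion > 0)
  if (!all(c("high", "low") %in% receiver_subclasses$survival_class))
    stop("receiver subclasses must include both survival classes")
  sender_types <- paste0("Sender", seq_len(n_sender_types))
  default_senders <- c("MullerGlia", "Astrocyte", "Microglia",
                       "Amacrine", "Bipolar", "Photoreceptor")
  sender_types[seq_len(min(n_sender_types, length(default_senders)))] <-
    default_senders[seq_len(min(n_sender_types, length(default_senders)))]
  labels <- c(sender_types, receiver_subclasses$name)

  n_mito <- max(1L, round(mito_gene_fraction * n_genes))
  mito_genes <- paste0("mt-", seq_len(n_mito))
  marker_genes <- unlist(lapply(labels, function(l)
    paste0("mk_", l, "_", seq_len(n_marker_genes_per_type))))
  n_generic <- n_genes - n_mito - length(marker_genes)
  if (n_generic < 40)
    stop("n_genes too small for the marker/mito layout")
  generic_genes <- sprintf("g%04d", seq_len(n_generic))
  gene_ids <- c(marker_genes, generic_genes, mito_genes)

  if (is.null(planted_pairs)) {
    n_pl <- min(6L, n_sender_types)
    planted_pairs <- data.frame(
      ligand = generic_genes[n_generic - seq_len(n_pl) + 1L],
      receptor = generic_genes[n_generic - n_pl - seq_len(n_pl) + 1L],
      sender = sender_types[seq_len(n_pl)],
      target_survival_class = "high",
      effect_size = 4,
      dynamics = rep(c("preset", "induced"), length.out = n_pl),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(planted_pairs$effect_size >= 1),
            all(planted_pairs$dynamics %in% c("preset", "induced")),
            all(planted_pairs$target_survival_class %in%
                c("high", "low", "both")))
  missing_genes <- setdiff(c(planted_pairs$ligand, planted_pairs$receptor),
                           gene_ids)
  if (length(missing_genes))
    stop("planted genes absent from the gene universe: ",
         paste(missing_genes, collapse = ", "))
  if (!all(planted_pairs$sender %in% sender_types))
    stop("planted senders must be sender cell types")

  if (is.null(planted_loops)) {
    n_loop <- min(2L, nrow(planted_pairs))
    reserved <- c(planted_pairs$ligand, planted_pairs$receptor)
    pool <- setdiff(generic_genes, reserved)
    planted_loops <- data.frame(
      ligand = planted_pairs$ligand[seq_len(n_loop)],
      receptor = planted_pairs$receptor[seq_len(n_loop)],
      back_ligand = pool[length(pool) - seq_len(n_loop) + 1L],
      back_receptor = pool[length(pool) - n_loop - seq_len(n_loop) + 1L],
      tf = pool[length(pool) - 2L * n_loop - seq_len(n_loop) + 1L],
      stringsAsFactors = FALSE)
  }
  if (nrow(planted_loops)) {
    loop_genes <- c(planted_loops$back_ligand, planted_loops$back_receptor,
                    planted_loops$tf)
    missing_genes <- setdiff(loop_genes, gene_ids)
    if (length(missing_genes))
      stop("planted loop genes absent from the gene universe: ",
           paste(missing_genes, collapse = ", "))
  }

  structure(list(
    sender_types = sender_types,
    receiver_subclasses = receiver_subclasses,
    labels = labels,
    cells_per_type_per_timepoint = cells_per_type_per_timepoint,
    n_genes = n_genes, gene_ids = gene_ids,
    marker_genes = marker_genes, generic_genes = generic_genes,
    mito_genes = mito_genes,
    n_marker_genes_per_type = n_marker_genes_per_type,
    mito_inflated_fraction = mito_inflated_fraction,
    mito_inflation = mito_inflation,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    marker_boost = marker_boost,
    planted_pairs = planted_pairs, planted_loops = planted_loops,
    n_decoy_pairs = n_decoy_pairs,
    timepoints = timepoints, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a labelled synthetic atlas
#'
#' Draws the count matrix described by a \code{\link{synthetic_config}}
#' and returns it together with the full ground truth. Identical configs
#' (including the seed) produce identical output.
#'
#' @param config a \code{synthetic_config}.
#' @return list with \code{matrix} (a \code{cell_matrix}) and
#'   \code{truth} (planted pairs/loops, the ligand-receptor pair table
#'   with decoys flagged, the signalling network table, the marker map,
#'   and the expected unboosted group means of the planted genes).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- config$gene_ids
  n_genes <- length(genes)
  labels <- config$labels
  tps <- config$timepoints
  subs <- config$receiver_subclasses
  per_group <- config$cells_per_type_per_timepoint

  groups <- expand.grid(label = labels, timepoint = tps,
                        stringsAsFactors = FALSE)
  n_groups <- nrow(groups)
  n_cells <- n_groups * per_group

  # --- group-level expression multipliers -------------------------------
  flat_genes <- unique(c(config$planted_pairs$ligand,
                         config$planted_pairs$receptor,
                         config$planted_loops$back_ligand,
                         config$planted_loops$back_receptor,
                         config$planted_loops$tf,
                         config$mito_genes))
  major_type <- ifelse(labels %in% subs$name, "RGC", labels)
  type_mult <- matrix(1, n_genes, length(labels),
                      dimnames = list(genes, labels))
  generic_free <- setdiff(config$generic_genes, flat_genes)
  for (mt in unique(major_type)) {
    mult <- stats::rlnorm(length(generic_free), 0, 1.25)
    for (lab in labels[major_type == mt])
      type_mult[generic_free, lab] <- mult *
        stats::rlnorm(length(generic_free), 0, 0.1)
  }
  for (lab in labels) {
    mk <- paste0("mk_", lab, "_",
                 seq_len(config$n_marker_genes_per_type))
    type_mult[mk, lab] <- config$marker_boost
  }

  gmult <- matrix(1, n_genes, n_groups,
                  dimnames = list(genes, paste(groups$label,
                                               groups$timepoint,
                                               sep = "@")))
  for (j in seq_len(n_groups)) {
    jit <- rep(1, n_genes)
    jit[match(generic_free, genes)] <-
      stats::rlnorm(length(generic_free), 0, 0.15)
    gmult[, j] <- type_mult[, groups$label[j]] * jit
  }

  # --- planted interaction boosts ---------------------------------------
  post_tps <- tps[-1L]
  for (i in seq_len(nrow(config$planted_pairs))) {
    pp <- config$planted_pairs[i, ]
    boost_tps <- if (pp$dynamics == "preset") tps else post_tps
    targets <- switch(pp$target_survival_class,
                      high = subs$name[subs$survival_class == "high"],
                      low = subs$name[subs$survival_class == "low"],
                      both = subs$name)
    sj <- groups$label == pp$sender & groups$timepoint %in% boost_tps
    gmult[pp$ligand, sj] <- gmult[pp$ligand, sj] * pp$effect_size
    rj <- groups$label %in% targets & groups$timepoint %in% boost_tps
    gmult[pp$receptor, rj] <- gmult[pp$receptor, rj] * pp$effect_size
  }

  # --- per-cell draws ----------------------------------------------------
  cell_group <- rep(seq_len(n_groups), each = per_group)
  lib <- stats::rlnorm(n_cells, meanlog = -0.3^2 / 2, sdlog = 0.3)
  mu <- (config$nb_mean * gmult)[, cell_group] *
    rep(lib, each = n_genes)
  mito_idx <- match(config$mito_genes, genes)
  n_inflated <- round(config$mito_inflated_fraction * n_cells)
  inflated <- sort(sample.int(n_cells, n_inflated))
  mu[mito_idx, inflated] <- mu[mito_idx, inflated] * config$mito_inflation
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = config$nb_dispersion),
                   n_genes, n_cells)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(genes, cell_ids)

  lab_per_cell <- groups$label[cell_group]
  is_sub <- lab_per_cell %in% subs$name
  meta <- data.frame(
    cell_id = cell_ids,
    cell_type = ifelse(is_sub, "RGC", lab_per_cell),
    subclass = ifelse(is_sub, lab_per_cell, NA_character_),
    survival_class = ifelse(
      is_sub, subs$survival_class[match(lab_per_cell, subs$name)],
      NA_character_),
    timepoint = groups$timepoint[cell_group],
    condition = ifelse(groups$timepoint[cell_group] == tps[1L],
                       "sham", "ONC"),
    mito_inflated = seq_len(n_cells) %in% inflated,
    stringsAsFactors = FALSE)

  # --- ground-truth companion tables ------------------------------------
  reserved <- unique(c(flat_genes, config$marker_genes))
  pool <- setdiff(config$generic_genes, reserved)
  decoy_idx <- sample.int(length(pool) - length(pool) %% 2)
  half <- length(decoy_idx) %/% 2
  n_dec <- min(config$n_decoy_pairs, half)
  decoys <- data.frame(ligand = pool[decoy_idx[seq_len(n_dec)]],
                       receptor = pool[decoy_idx[half + seq_len(n_dec)]],
                       stringsAsFactors = FALSE)
  lr_pairs <- rbind(
    cbind(config$planted_pairs[, c("ligand", "receptor")],
          is_planted = TRUE, is_loop_back = FALSE),
    cbind(decoys, is_planted = FALSE, is_loop_back = FALSE))
  if (nrow(config$planted_loops))
    lr_pairs <- rbind(lr_pairs, data.frame(
      ligand = config$planted_loops$back_ligand,
      receptor = config$planted_loops$back_receptor,
      is_planted = FALSE, is_loop_back = TRUE,
      stringsAsFactors = FALSE))
  rownames(lr_pairs) <- NULL

  network <- data.frame(source = character(), target = character(),
                        kind = character(), stringsAsFactors = FALSE)
  if (nrow(config$planted_loops)) {
    pl <- config$planted_loops
    network <- rbind(
      data.frame(source = pl$receptor, target = pl$tf,
                 kind = "signaling", stringsAsFactors = FALSE),
      data.frame(source = pl$tf, target = pl$back_ligand,
                 kind = "regulatory", stringsAsFactors = FALSE))
  }
  # a few decoy relay edges among generic genes
  if (length(pool) >= 8) {
    extra <- pool[seq_len(6)]
    network <- rbind(network, data.frame(
      source = extra[c(1, 2, 3)], target = extra[c(4, 5, 6)],
      kind = "signaling", stringsAsFactors = FALSE))
  }

  markers <- stats::setNames(lapply(labels, function(l)
    paste0("mk_", l, "_", seq_len(config$n_marker_genes_per_type))),
    labels)

  planted_gene_ids <- unique(c(config$planted_pairs$ligand,
                               config$planted_pairs$receptor))
  truth <- list(
    config = config,
    labels = lab_per_cell,
    planted_pairs = config$planted_pairs,
    planted_loops = config$planted_loops,
    lr_pairs = lr_pairs,
    network = network,
    markers = markers,
    group_multiplier = gmult[planted_gene_ids, , drop = FALSE],
    baseline_mean = config$nb_mean,
    mito_inflated_cells = cell_ids[inflated])

  list(matrix = cell_matrix(counts, meta), truth = truth)
}

#' Write a synthetic atlas to disk
#'
#' Emits the 10x-style MTX triplet plus cell metadata (via
#' \code{\link{write_counts}}), the ligand-receptor pair table and
#' signalling network as TSV, the marker map as JSON, and a ground-truth
#' JSON (planted pairs and loops).
#'
#' @param atlas output of \code{\link{generate_atlas}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(atlas$matrix, dir)
  utils::write.table(atlas$truth$lr_pairs,
                     file.path(dir, "lr_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(atlas$truth$network,
                     file.path(dir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(atlas$truth$markers,
                       file.path(dir, "markers.json"))
  jsonlite::write_json(
    list(planted_pairs = atlas$truth$planted_pairs,
         planted_loops = atlas$truth$planted_loops),
    file.path(dir, "ground_truth.json"), dataframe = "rows")
  invisible(dir)
}

# deterministic blob of exactly `area` pixels grown outward from a centre
dot_offsets <- function(area) {
  r <- 0L
  repeat {
    cand <- expand.grid(dr = -r:r, dc = -r:r)
    cand$d2 <- cand$dr^2 + cand$dc^2
    cand <- cand[order(cand$d2, cand$dr, cand$dc), ]
    if (nrow(cand) >= area) return(cand[seq_len(area), c("dr", "dc")])
    r <- r + 1L
  }
}

#' Generate a synthetic RNAscope dot image
#'
#' Places \code{n_dots} identical non-overlapping blobs of exactly
#' \code{dot_area_px} pixels, each adding \code{dot_intensity} per pixel
#' on top of a constant background. Placement is rejection-sampled with a
#' one-pixel separation margin so dots stay distinct under
#' 8-connectivity; if the dots cannot be placed after bounded retries, an
#' error is raised. Identical seeds give identical images.
#'
#' @param n_dots number of dots (0 gives pure background).
#' @param dot_intensity per-pixel signal added by a dot.
#' @param dot_area_px pixels per dot.
#' @param background_level constant background intensity.
#' @param image_shape c(rows, cols).
#' @param noise_sd optional Gaussian noise SD added everywhere
#'   (truncated at 0); default 0 (deterministic closed-form image).
#' @param seed integer RNG seed.
#' @return list with \code{field} (a \code{dot_field} with the exact
#'   background and a threshold halfway between background and dot level)
#'   and \code{truth} (n_dots, per-dot integrated signal intensity,
#'   dot_area_px, background_level, centre coordinates).
#' @export
generate_dot_image <- function(n_dots, dot_intensity = 50,
                               dot_area_px = 9, background_level = 2,
                               image_shape = c(96, 96), noise_sd = 0,
                               seed = 1L) {
  stopifnot(n_dots >= 0, dot_intensity > 0, dot_area_px >= 1)
  set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  img <- matrix(background_level, nr, nc)
  offs <- dot_offsets(dot_area_px)
  pad <- max(abs(unlist(offs))) + 1L
  occupied <- matrix(FALSE, nr, nc)
  centres <- matrix(NA_integer_, n_dots, 2)
  max_tries <- 1000L * max(1L, n_dots)
  tries <- 0L
  placed <- 0L
  while (placed < n_dots) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n_dots, " non-overlapping dots in a ",
           nr, "x", nc, " image")
    cr <- sample.int(nr - 2L * pad, 1L) + pad
    cc <- sample.int(nc - 2L * pad, 1L) + pad
    rr <- cr + offs$dr; cc2 <- cc + offs$dc
    # one-pixel exclusion margin around the blob
    block_r <- pmax(1L, pmin(nr, rep(rr, each = 9) +
                               rep(-1:1, times = 3 * length(rr))))
    block_c <- pmax(1L, pmin(nc, rep(cc2, each = 9) +
                               rep(rep(-1:1, each = 3), length(cc2))))
    if (any(occupied[cbind(block_r, block_c)])) next
    occupied[cbind(block_r, block_c)] <- TRUE
    img[cbind(rr, cc2)] <- img[cbind(rr, cc2)] + dot_intensity
    placed <- placed + 1L
    centres[placed, ] <- c(cr, cc)
  }
  if (noise_sd > 0)
    img <- pmax(0, img + matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                nr, nc))
  field <- dot_field(img, background_mean = background_level,
                     detect_threshold = background_level +
                       dot_intensity / 2)
  list(field = field,
       truth = list(n_dots = n_dots,
                    dot_signal_intensity = dot_intensity * dot_area_px,
                    dot_area_px = dot_area_px,
                    background_level = background_level,
                    centres = centres))
}

#' Write a dot field as a PNG image
#'
#' Intensities are rescaled to [0, 1] by the image maximum.
#'
#' @param f a \code{dot_field}.
#' @param path output .png path.
#' @return \code{path}, invisibly.
#' @export
write_dot_image <- function(f, path) {
  img <- f$intensity
  mx <- max(img)
  png::writePNG(if (mx > 0) img / mx else img, path)
  invisible(path)
}
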