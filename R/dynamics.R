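#' Trajectory matrix from a score table
#'
#' One row per (sender, receiver, pair), one column per timepoint in the
#' declared order, values are interaction scores.
#'
#' @param table a \code{score_table}.
#' @param timepoints timepoint order; default: the table's declared order.
#' @return numeric matrix with informative rownames
#'   ("sender|receiver|ligand-receptor").
#' @export
score_trajectories <- function(table, timepoints = NULL) {
  stopifnot(inherits(table, "score_table"))
  if (is.null(timepoints)) timepoints <- attr(table, "timepoints")
  key <- paste(table$sender, table$receiver,
               paste(table$ligand, table$receptor, sep = "-"), sep = "|")
  ukey <- unique(key)
  mat <- matrix(NA_real_, nrow = length(ukey), ncol = length(timepoints),
                dimnames = list(ukey, timepoints))
  mat[cbind(match(key, ukey), match(table$timepoint, timepoints))] <-
    table$S_LR
  if (anyNA(mat)) stop("incomplete trajectories: missing timepoints")
  mat
}

#' Variable interactions by fold change between timepoints
#'
#' A trajectory is variable when its fold change between some ordered pair
#' of timepoints exceeds \code{fc_min}: max over (i, j) of
#' (s_i + pseudocount) / (s_j + pseudocount) > fc_min. The pseudocount
#' keeps ratios of near-zero scores finite (default 0.05 on the [0, 1]
#' score scale).
#'
#' @param trajs trajectory matrix (rows = trajectories).
#' @param fc_min fold-change threshold, exclusive (default 1.2).
#' @param pseudocount added to both sides of the ratio.
#' @return logical vector, one entry per row of \code{trajs}.
#' @export
variable_interactions <- function(trajs, fc_min = 1.2, pseudocount = 0.05) {
  trajs <- as.matrix(trajs)
  hi <- apply(trajs, 1L, max) + pseudocount
  lo <- apply(trajs, 1L, min) + pseudocount
  hi / lo > fc_min
}

#' Cluster score trajectories into temporal groups
#'
#' Rows are z-scored, pairwise distances are 1 - Pearson correlation, and
#' average-linkage hierarchical clustering is cut at \code{k} groups.
#' Constant trajectories (zero variance) cannot be z-scored and are
#' rejected; filter with \code{\link{variable_interactions}} first.
#'
#' @param trajs trajectory matrix.
#' @param k number of groups (default 4).
#' @return integer vector of group labels, named by trajectory.
#' @export
cluster_trajectories <- function(trajs, k = 4) {
  trajs <- as.matrix(trajs)
  if (k > nrow(trajs))
    stop("k = ", k, " exceeds the number of trajectories (", nrow(trajs), ")")
  if (k < 1) stop("k must be positive")
  sds <- apply(trajs, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant trajectories cannot be clustered on correlation ",
         "distance; remove them first")
  z <- t(scale(t(trajs)))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, k = k)
}

#' Preset versus induced classification of a differential interaction
#'
#' A protective interaction is \emph{preset} when it is already stronger
#' toward high-survival receivers before injury, and \emph{induced} when
#' the advantage only appears after injury. pre_diff is the high-minus-low
#' difference of mean subclass scores at the pre-injury timepoint;
#' post_diff is the same difference of per-subclass maxima over the
#' post-injury timepoints. Call: preset if pre_diff > delta; induced if
#' pre_diff <= delta and post_diff > delta; neither otherwise.
#'
#' @param table a \code{score_table} at subclass granularity.
#' @param sender sender cell type.
#' @param ligand,receptor the pair.
#' @param params a \code{differential_params} (supplies the subclass sets).
#' @param delta decision threshold (default 0.25, consistent with the
#'   protective cutoff).
#' @param sham_timepoint label of the pre-injury timepoint
#'   (default "sham").
#' @return one-row data.frame: sender, ligand, receptor, pre_diff,
#'   post_diff, call.
#' @export
preset_induced <- function(table, sender, ligand, receptor, params,
                           delta = 0.25, sham_timepoint = "sham") {
  stopifnot(inherits(table, "score_table"),
            inherits(params, "differential_params"))
  tps <- attr(table, "timepoints")
  if (is.null(tps)) tps <- unique(table$timepoint)
  if (!sham_timepoint %in% tps)
    stop("pre-injury timepoint '", sham_timepoint, "' not present")
  post_tps <- setdiff(tps, sham_timepoint)
  if (!length(post_tps)) stop("no post-injury timepoints present")

  group_val <- function(subclasses, timepoint_set, combine) {
    vals <- vapply(subclasses, function(sc) {
      rows <- table$sender == sender & table$receiver == sc &
        table$ligand == ligand & table$receptor == receptor &
        table$timepoint %in% timepoint_set
      if (!any(rows))
        stop("no scores for subclass '", sc, "' at requested timepoints")
      combine(table$S_LR[rows])
    }, numeric(1))
    mean(vals)
  }
  pre_diff <- group_val(params$high_subclasses, sham_timepoint, max) -
    group_val(params$low_subclasses, sham_timepoint, max)
  post_diff <- group_val(params$high_subclasses, post_tps, max) -
    group_val(params$low_subclasses, post_tps, max)
  call <- if (pre_diff > delta) "preset"
          else if (post_diff > delta) "induced" else "neither"
  data.frame(sender = sender, ligand = ligand, receptor = receptor,
             pre_diff = pre_diff, post_diff = post_diff, call = call,
             stringsAsFactors = FALSE)
}
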