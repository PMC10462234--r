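#' Scoring parameters
#'
#' @param detect_min minimum detection rate for ligand (in sender) and
#'   receptor (in receiver); default 0.10.
#' @param score_min minimum of the max-over-timepoints interaction score a
#'   pair must reach to be kept; default 0.5, boundary-inclusive.
#' @param beta feedback-loop bonus coefficient; default 0.5.
#' @param loop_combine how multiple loops for one pair are combined:
#'   \code{"max"} (default) or \code{"sum"} of back-pair scores.
#' @param min_cells groups smaller than this are scored but flagged
#'   low-confidence; default 10.
#' @return a \code{scoring_params} object.
#' @export
scoring_params <- function(detect_min = 0.10, score_min = 0.5,
                           beta = 0.5, loop_combine = c("max", "sum"),
                           min_cells = 10) {
  stopifnot(detect_min >= 0, detect_min <= 1,
            score_min >= 0, score_min <= 1, beta >= 0)
  loop_combine <- match.arg(loop_combine)
  structure(list(detect_min = detect_min, score_min = score_min,
                 beta = beta, loop_combine = loop_combine,
                 min_cells = min_cells),
            class = "scoring_params")
}

# Mean normalized expression, detection rate and size of every
# (label, timepoint) group. Returns list(mean, det, n) where mean/det are
# genes x group matrices, group names are "<label>@<timepoint>".
group_summaries <- function(m, level = "subclass") {
  labels <- cell_labels(m, level)
  tps <- as.character(m$cell_meta$timepoint)
  grp <- paste(labels, tps, sep = "@")
  grp_f <- factor(grp, levels = unique(grp))
  ind <- Matrix::sparseMatrix(i = seq_along(grp_f),
                              j = as.integer(grp_f), x = 1,
                              dims = c(length(grp_f), nlevels(grp_f)))
  n <- Matrix::colSums(ind)
  norm <- normalize_counts(m)
  mean_mat <- as.matrix(norm %*% ind) / rep(n, each = nrow(norm))
  det_mat <- as.matrix((m$counts > 0) %*% ind) / rep(n, each = nrow(norm))
  dimnames(mean_mat) <- dimnames(det_mat) <-
    list(rownames(m$counts), levels(grp_f))
  list(mean = mean_mat, det = det_mat, n = n,
       labels = unique(labels), timepoints = unique(tps))
}

# Per-gene min-max scaling of a genes x groups mean matrix to [0, 1].
# A gene with identical means in every group (no between-group contrast)
# scales to 0.
minmax_scale_rows <- function(mean_mat) {
  lo <- apply(mean_mat, 1L, min)
  hi <- apply(mean_mat, 1L, max)
  rng <- hi - lo
  scaled <- (mean_mat - lo) / ifelse(rng > 0, rng, 1)
  scaled[rng == 0, ] <- 0
  scaled
}

#' Base ligand-receptor interaction scores
#'
#' For every (sender, receiver, pair, timepoint) combination, the base
#' score is s0 = sqrt(l * r), where l and r are the mean normalized
#' expressions of the ligand in the sender group and the receptor in the
#' receiver group at that timepoint, each min-max scaled to [0, 1] per gene
#' across all (group, timepoint) means of the dataset. Scores therefore lie
#' in [0, 1], with 1 meaning both ends sit at their strongest group.
#'
#' @param m a \code{cell_matrix} with timepoint annotation.
#' @param lr an \code{lr_database}; pairs with either gene absent from the
#'   matrix are dropped.
#' @param senders,receivers label sets to score; NULL means all labels at
#'   the chosen granularity.
#' @param receiver_level \code{"cell_type"} scores receivers as major
#'   types; \code{"subclass"} (default) scores annotated subclasses
#'   individually (required for the differential analysis).
#' @param params a \code{scoring_params} object.
#' @return a \code{score_table}: long data.frame with columns sender,
#'   receiver, ligand, receptor, timepoint, s0, S_LR (equal to s0 until
#'   loop adjustment), det_ligand, det_receptor, n_sender, n_receiver,
#'   low_confidence.
#' @export
score_interactions <- function(m, lr, senders = NULL, receivers = NULL,
                               receiver_level = c("subclass", "cell_type"),
                               params = scoring_params()) {
  stopifnot(inherits(m, "cell_matrix"))
  receiver_level <- match.arg(receiver_level)
  gs <- group_summaries(m, receiver_level)
  scaled <- minmax_scale_rows(gs$mean)
  tps <- gs$timepoints
  labels <- gs$labels
  if (is.null(senders)) senders <- labels
  if (is.null(receivers)) receivers <- labels
  missing_lab <- setdiff(c(senders, receivers), labels)
  if (length(missing_lab))
    stop("unknown group label(s): ", paste(missing_lab, collapse = ", "))

  lr <- as.data.frame(lr)
  lr <- lr[lr$ligand %in% rownames(scaled) &
           lr$receptor %in% rownames(scaled), , drop = FALSE]

  combos <- expand.grid(timepoint = tps, pair = seq_len(nrow(lr)),
                        receiver = receivers, sender = senders,
                        stringsAsFactors = FALSE)
  if (!nrow(combos) || !nrow(lr)) {
    out <- data.frame(sender = character(), receiver = character(),
                      ligand = character(), receptor = character(),
                      timepoint = character(), s0 = numeric(),
                      S_LR = numeric(), det_ligand = numeric(),
                      det_receptor = numeric(), n_sender = integer(),
                      n_receiver = integer(), low_confidence = logical())
    class(out) <- c("score_table", "data.frame")
    return(out)
  }
  s_grp <- paste(combos$sender, combos$timepoint, sep = "@")
  r_grp <- paste(combos$receiver, combos$timepoint, sep = "@")
  known_grp <- colnames(scaled)
  if (!all(s_grp %in% known_grp) || !all(r_grp %in% known_grp)) {
    bad <- setdiff(unique(c(s_grp, r_grp)), known_grp)
    stop("empty group(s) at requested (label, timepoint): ",
         paste(bad, collapse = ", "))
  }
  lig <- lr$ligand[combos$pair]
  rec <- lr$receptor[combos$pair]
  l_val <- scaled[cbind(lig, s_grp)]
  r_val <- scaled[cbind(rec, r_grp)]
  s0 <- sqrt(l_val * r_val)
  out <- data.frame(
    sender = combos$sender, receiver = combos$receiver,
    ligand = lig, receptor = rec, timepoint = combos$timepoint,
    s0 = s0, S_LR = s0,
    det_ligand = gs$det[cbind(lig, s_grp)],
    det_receptor = gs$det[cbind(rec, r_grp)],
    n_sender = as.integer(gs$n[s_grp]),
    n_receiver = as.integer(gs$n[r_grp]),
    stringsAsFactors = FALSE)
  out$low_confidence <- out$n_sender < params$min_cells |
    out$n_receiver < params$min_cells
  out <- out[order(out$sender, out$receiver, out$ligand, out$receptor,
                   match(out$timepoint, tps)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "timepoints") <- tps
  attr(out, "receiver_level") <- receiver_level
  class(out) <- c("score_table", "data.frame")
  out
}

#' Loop-adjusted interaction score
#'
#' Feedback support multiplies the base score: S_LR = min(1, s0 * (1 +
#' beta * B)) where B is the combined back-pair score (max by default, 0
#' when no loop exists). Monotone in beta and in the back scores; the cap
#' keeps S_LR in [0, 1].
#'
#' @param s0 base score(s) in [0, 1].
#' @param back_scores numeric vector of back-pair base scores (may be
#'   empty).
#' @param beta loop bonus coefficient.
#' @param loop_combine \code{"max"} or \code{"sum"}.
#' @return adjusted score(s).
#' @export
loop_adjusted_score <- function(s0, back_scores = numeric(), beta = 0.5,
                                loop_combine = c("max", "sum")) {
  loop_combine <- match.arg(loop_combine)
  b <- if (!length(back_scores)) 0
       else if (loop_combine == "max") max(back_scores)
       else sum(back_scores)
  pmin(1, s0 * (1 + beta * b))
}

#' Apply feedback-loop adjustment across a score table
#'
#' For each scored (sender, receiver, pair), feedback loops are detected in
#' the receiver's active subgraph (see \code{\link{find_feedback_loops}})
#' and the pair's scores at each timepoint are boosted by the back pairs'
#' base scores in the reverse direction (receiver as sender) at the same
#' timepoint.
#'
#' @param table a \code{score_table} from \code{score_interactions}.
#' @param m the \code{cell_matrix} the table was scored on.
#' @param lr the \code{lr_database}.
#' @param g the full signalling graph (igraph).
#' @param params a \code{scoring_params}.
#' @param max_path_len maximum receiver-side path length.
#' @return the table with updated \code{S_LR} and a \code{n_loops} column.
#' @export
add_loop_adjustment <- function(table, m, lr, g,
                                params = scoring_params(),
                                max_path_len = 4) {
  stopifnot(inherits(table, "score_table"))
  if (!nrow(table)) { table$n_loops <- integer(0); return(table) }
  # reverse-direction base scores for back pairs
  level <- attr(table, "receiver_level")
  if (is.null(level)) level <- "subclass"
  rev_tab <- score_interactions(
    m, lr, senders = unique(table$receiver),
    receivers = unique(table$sender),
    receiver_level = level, params = params)
  rev_key <- paste(rev_tab$sender, rev_tab$receiver, rev_tab$ligand,
                   rev_tab$receptor, rev_tab$timepoint, sep = "\r")
  rev_s0 <- stats::setNames(rev_tab$s0, rev_key)

  labels <- unique(c(table$sender, table$receiver))
  subgraphs <- lapply(stats::setNames(labels, labels), function(lab)
    active_subgraph(g, m, lab, params$detect_min))

  table$n_loops <- 0L
  trio <- paste(table$sender, table$receiver, table$ligand,
                table$receptor, sep = "\r")
  for (key in unique(trio)) {
    rows <- which(trio == key)
    fw <- list(ligand = table$ligand[rows[1]],
               receptor = table$receptor[rows[1]],
               sender = table$sender[rows[1]],
               receiver = table$receiver[rows[1]])
    loops <- find_feedback_loops(
      fw, lr, g_receiver = subgraphs[[fw$receiver]],
      g_sender = subgraphs[[fw$sender]], m = m,
      detect_min = params$detect_min, max_path_len = max_path_len)
    table$n_loops[rows] <- nrow(loops)
    if (!nrow(loops)) next
    for (i in rows) {
      bk <- paste(fw$receiver, fw$sender, loops$back_ligand,
                  loops$back_receptor, table$timepoint[i], sep = "\r")
      back <- rev_s0[bk]
      back <- back[!is.na(back)]
      table$S_LR[i] <- loop_adjusted_score(
        table$s0[i], back, params$beta, params$loop_combine)
    }
  }
  table
}

#' Filter a score table on detection and score strength
#'
#' A (sender, receiver, pair) survives iff its ligand is detected in at
#' least \code{detect_min} of the sender's cells, its receptor in at least
#' \code{detect_min} of the receiver's cells (each taken as the max over
#' timepoints of the per-timepoint rates), and its interaction score
#' reaches at least \code{score_min} at some timepoint (boundary
#' inclusive). All timepoints of surviving keys are retained; the filter is
#' idempotent.
#'
#' @param table a \code{score_table}.
#' @param params a \code{scoring_params}.
#' @return the filtered \code{score_table}.
#' @export
filter_pairs <- function(table, params = scoring_params()) {
  stopifnot(inherits(table, "score_table"))
  if (!nrow(table)) return(table)
  key <- paste(table$sender, table$receiver, table$ligand, table$receptor,
               sep = "\r")
  keep_key <- vapply(split(seq_len(nrow(table)), key), function(rows) {
    max(table$det_ligand[rows]) >= params$detect_min &&
      max(table$det_receptor[rows]) >= params$detect_min &&
      max(table$S_LR[rows]) >= params$score_min
  }, logical(1))
  out <- table[keep_key[key], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "timepoints") <- attr(table, "timepoints")
  attr(out, "receiver_level") <- attr(table, "receiver_level")
  out
}

#' Overall communication score between two cell groups
#'
#' Sum of interaction scores over the surviving pairs for one (sender,
#' receiver, timepoint). Apply \code{\link{filter_pairs}} first.
#'
#' @param table a filtered \code{score_table}.
#' @param sender,receiver,timepoint the cell-group pair and timepoint.
#' @return the summed score (0 when no pairs survive).
#' @export
overall_score <- function(table, sender, receiver, timepoint) {
  stopifnot(inherits(table, "score_table"))
  rows <- table$sender == sender & table$receiver == receiver &
    table$timepoint == timepoint
  sum(table$S_LR[rows])
}

#' Write a score table as long-format TSV
#'
#' @param table a \code{score_table}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
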