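#' Differential interaction parameters
#'
#' Receiver subclasses are partitioned into a high-survival set and a
#' low-survival set; an interaction is called protective when its
#' differential score exceeds \code{cutoff_hi} and depleted when it falls
#' below \code{cutoff_lo}. Cutoff comparisons are strict: a score exactly
#' at a cutoff is neutral. Defaults mirror the injury-resilient subclasses
#' (ipRGC, alphaRGC, Gpr88RGC) against the remaining, vulnerable ones.
#'
#' @param high_subclasses,low_subclasses disjoint, non-empty label sets.
#' @param cutoff_hi,cutoff_lo protective / depleted cutoffs
#'   (defaults 0.25 and -0.25).
#' @return a \code{differential_params} object.
#' @export
differential_params <- function(high_subclasses, low_subclasses,
                                cutoff_hi = 0.25, cutoff_lo = -0.25) {
  stopifnot(cutoff_lo < cutoff_hi,
            length(high_subclasses) > 0, length(low_subclasses) > 0)
  if (length(intersect(high_subclasses, low_subclasses)))
    stop("high and low subclass sets must be disjoint")
  structure(list(high_subclasses = as.character(high_subclasses),
                 low_subclasses = as.character(low_subclasses),
                 cutoff_hi = cutoff_hi, cutoff_lo = cutoff_lo),
            class = "differential_params")
}

# max-over-timepoints score per subclass for one (sender, pair)
subclass_maxima <- function(table, sender, ligand, receptor, subclasses) {
  vapply(subclasses, function(sc) {
    rows <- table$sender == sender & table$receiver == sc &
      table$ligand == ligand & table$receptor == receptor
    if (!any(rows))
      stop("no scored timepoints for subclass '", sc, "' (sender ",
           sender, ", pair ", ligand, "-", receptor, ")")
    max(table$S_LR[rows])
  }, numeric(1))
}

#' Differential interaction score between survival classes
#'
#' For one sender cell type and one ligand-receptor pair: take each
#' receiver subclass's maximum interaction score over timepoints, average
#' within the high-survival set and within the low-survival set, and
#' report the difference. The score is antisymmetric under swapping the
#' two sets. Calls: protective if the difference > cutoff_hi, depleted if
#' < cutoff_lo, neutral otherwise.
#'
#' @param table a \code{score_table} scored at subclass granularity.
#' @param sender sender cell type.
#' @param ligand,receptor the pair.
#' @param params a \code{differential_params}.
#' @return a one-row data.frame: sender, ligand, receptor, mean_high,
#'   mean_low, dslr, call.
#' @export
dslr <- function(table, sender, ligand, receptor, params) {
  stopifnot(inherits(table, "score_table"),
            inherits(params, "differential_params"))
  hi <- subclass_maxima(table, sender, ligand, receptor,
                        params$high_subclasses)
  lo <- subclass_maxima(table, sender, ligand, receptor,
                        params$low_subclasses)
  d <- mean(hi) - mean(lo)
  call <- if (d > params$cutoff_hi) "protective"
          else if (d < params$cutoff_lo) "depleted" else "neutral"
  data.frame(sender = sender, ligand = ligand, receptor = receptor,
             mean_high = mean(hi), mean_low = mean(lo), dslr = d,
             call = call, stringsAsFactors = FALSE)
}

#' Differential table over all scored (sender, pair) combinations
#'
#' Computes \code{\link{dslr}} for every (sender, ligand, receptor) present
#' in the table, restricted to combinations scored for every listed
#' subclass. Records are sorted by differential score, descending, within
#' each sender.
#'
#' @param table a filtered \code{score_table} at subclass granularity.
#' @param params a \code{differential_params}.
#' @param senders optional restriction of sender types; default: all
#'   senders in the table that are not themselves listed subclasses.
#' @return data.frame of differential records.
#' @export
protective_table <- function(table, params, senders = NULL) {
  stopifnot(inherits(table, "score_table"))
  subclasses <- c(params$high_subclasses, params$low_subclasses)
  if (is.null(senders))
    senders <- setdiff(unique(table$sender), subclasses)
  sub <- table[table$sender %in% senders &
               table$receiver %in% subclasses, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(sender = character(), ligand = character(),
                      receptor = character(), mean_high = numeric(),
                      mean_low = numeric(), dslr = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  key <- unique(sub[, c("sender", "ligand", "receptor")])
  # keep only combinations scored for the full subclass panel
  complete <- vapply(seq_len(nrow(key)), function(i) {
    rows <- sub$sender == key$sender[i] & sub$ligand == key$ligand[i] &
      sub$receptor == key$receptor[i]
    all(subclasses %in% sub$receiver[rows])
  }, logical(1))
  key <- key[complete, , drop = FALSE]
  recs <- lapply(seq_len(nrow(key)), function(i)
    dslr(sub, key$sender[i], key$ligand[i], key$receptor[i], params))
  out <- do.call(rbind, recs)
  out <- out[order(out$sender, -out$dslr, out$ligand, out$receptor), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Non-redundant ranked interaction list across senders
#'
#' Deduplicates differential records by (ligand, receptor), keeping the
#' maximum differential score across senders; ranks by that maximum,
#' breaking ties by the number of supporting senders (more first) and then
#' lexicographically by pair; truncates to \code{top_n}.
#'
#' @param records differential records (rows of \code{\link{dslr}} output).
#' @param top_n number of pairs to keep; must be positive.
#' @param calls which calls count as support (default \code{"protective"};
#'   use \code{NULL} to rank all records).
#' @return data.frame: ligand, receptor, best_dslr, n_senders, senders
#'   (comma-separated).
#' @export
aggregate_nonredundant <- function(records, top_n = 47,
                                   calls = "protective") {
  if (top_n <= 0) stop("top_n must be positive")
  if (!is.null(calls)) records <- records[records$call %in% calls, ,
                                          drop = FALSE]
  if (!nrow(records))
    return(data.frame(ligand = character(), receptor = character(),
                      best_dslr = numeric(), n_senders = integer(),
                      senders = character(), stringsAsFactors = FALSE))
  key <- paste(records$ligand, records$receptor, sep = "\r")
  agg <- lapply(split(seq_len(nrow(records)), key), function(rows) {
    data.frame(ligand = records$ligand[rows[1]],
               receptor = records$receptor[rows[1]],
               best_dslr = max(records$dslr[rows]),
               n_senders = length(unique(records$sender[rows])),
               senders = paste(sort(unique(records$sender[rows])),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$best_dslr, -out$n_senders, out$ligand,
                   out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
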