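#' Survival-normalized subclass composition
#'
#' Raw subclass percentages computed within one condition are not
#' comparable across conditions that differ in overall cell death: a
#' subclass can keep its within-sample share while most of the sample has
#' died. Scaling each percentage by the condition's total survival rate
#' (determined externally, e.g. by immunostaining; 1.0 for an uninjured
#' control) puts the compositions on a common absolute scale:
#' adjusted_i = (count_i / sum(counts)) * survival_rate * 100. Adjusted
#' percentages always sum to survival_rate * 100, and ratios between
#' subclasses are unchanged.
#'
#' @param counts named non-negative integer vector of cells per subclass,
#'   or a data.frame with \code{subclass} and \code{count} columns.
#' @param survival_rate total survival rate of the condition, in (0, 1].
#' @return data.frame: subclass, count, raw_pct, adjusted_pct.
#' @export
normalize_by_survival <- function(counts, survival_rate = 1.0) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("subclass", "count") %in% names(counts)))
    counts <- stats::setNames(counts$count, counts$subclass)
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  if (!(survival_rate > 0 && survival_rate <= 1))
    stop("survival_rate must be in (0, 1]")
  raw_pct <- 100 * counts / total
  data.frame(subclass = names(counts), count = as.numeric(counts),
             raw_pct = as.numeric(raw_pct),
             adjusted_pct = as.numeric(raw_pct * survival_rate),
             stringsAsFactors = FALSE)
}

#' Survival-normalized composition for several conditions
#'
#' @param df data.frame with \code{condition}, \code{subclass},
#'   \code{count} and \code{survival_rate} columns (one rate per
#'   condition).
#' @return data.frame with adjusted percentages per condition.
#' @export
normalize_conditions <- function(df) {
  stopifnot(all(c("condition", "subclass", "count", "survival_rate") %in%
                names(df)))
  out <- lapply(split(df, df$condition), function(d) {
    rates <- unique(d$survival_rate)
    if (length(rates) != 1)
      stop("condition '", d$condition[1],
           "' has multiple survival rates")
    res <- normalize_by_survival(
      stats::setNames(d$count, d$subclass), rates)
    cbind(condition = d$condition[1], res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
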