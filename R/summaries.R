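#' Posterior median point estimate
#'
#' The atlas point estimate is the posterior median of the ratio-scale
#' measure (SIR or EHR). Quantiles throughout use linear interpolation
#' between order statistics (R's default, "type 7"), so interval endpoints
#' are continuous in the draws.
#'
#' @param draws positive numeric vector of posterior draws for one area.
#' @return The sample median.
#' @export
point_estimate <- function(draws) {
  .assert(length(draws) >= 1, "draws must be non-empty")
  .assert(all(draws > 0), "ratio-scale draws must be positive")
  unname(quantile(draws, 0.5, type = 7, names = FALSE))
}

#' Equal-tailed credible interval
#'
#' Quantiles at `(1 - level/100)/2` and `1 - (1 - level/100)/2`. The atlas
#' uses 60% and 80% levels, chosen so that e.g. an 80% interval carries a
#' direct posterior probability of 0.8 of containing the true value.
#'
#' @param draws numeric vector of posterior draws for one area (>= 2).
#' @param level interval level in percent, in (0, 100).
#' @return Numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(draws, level = 80) {
  .assert(length(draws) >= 2, "need at least 2 draws")
  .assert(is.numeric(level) && length(level) == 1 && level > 0 && level < 100,
          "level must be in (0, 100)")
  a <- (1 - level / 100) / 2
  unname(quantile(draws, c(a, 1 - a), type = 7, names = FALSE))
}

#' Posterior probability of difference (PPD)
#'
#' The proportion of posterior draws of the ratio-scale measure that exceed
#' the national-average reference of 1. Draws exactly equal to the reference
#' count as half, removing directional bias in the tie case.
#'
#' @param draws numeric vector of posterior draws for one area.
#' @param reference ratio-scale threshold (default 1, the national average).
#' @return Probability in `[0, 1]`.
#' @export
ppd <- function(draws, reference = 1) {
  .assert(length(draws) >= 1, "draws must be non-empty")
  (sum(draws > reference) + 0.5 * sum(draws == reference)) / length(draws)
}

#' Folded confidence of difference
#'
#' `max(ppd, 1 - ppd)`: the probability that the area's measure differs from
#' the national average in its more probable direction. This is the V-plot
#' y-coordinate; 0.5 means maximal uncertainty, 1 near-certainty.
#'
#' @param p PPD value(s) in `[0, 1]`.
#' @return Value(s) in `[0.5, 1]`.
#' @export
v_confidence <- function(p) {
  .assert(.is_prob(p), "ppd must be in [0, 1]")
  pmax(p, 1 - p)
}

#' Classify an area's difference from the national average
#'
#' Maps the PPD to one of `likely_higher` (`ppd >= high`), `likely_lower`
#' (`ppd <= low`) or `uncertain`. The atlas phrases these as "likely" /
#' "unlikely" to be different from the national average; the numeric cutoffs
#' are configurable package defaults.
#'
#' @param p PPD value(s).
#' @param thresholds `c(low, high)` with `0 <= low < high <= 1`.
#' @return Character vector of categories.
#' @export
classify_difference <- function(p, thresholds = c(0.2, 0.8)) {
  .assert(.is_prob(p), "ppd must be in [0, 1]")
  .assert(length(thresholds) == 2 && thresholds[1] >= 0 &&
          thresholds[1] < thresholds[2] && thresholds[2] <= 1,
          "thresholds must satisfy 0 <= low < high <= 1")
  ifelse(p >= thresholds[2], "likely_higher",
         ifelse(p <= thresholds[1], "likely_lower", "uncertain"))
}

#' Summarize posterior draws for every area
#'
#' Computes the published per-area quantities: posterior median, 60% and 80%
#' equal-tailed credible intervals, PPD against the reference of 1, folded
#' confidence, and the difference category.
#'
#' @param draws a `posterior_draws` object (or a draws matrix with area ids
#'   as column names).
#' @param reference ratio-scale reference (default 1).
#' @param thresholds category cutoffs passed to [classify_difference].
#' @return Data frame of class `area_summary` with one row per area, columns
#'   `area_id, point, ci60_lo, ci60_hi, ci80_lo, ci80_hi, ppd, v_conf,
#'   category`, in the draws' area order.
#' @export
summarize_all <- function(draws, reference = 1, thresholds = c(0.2, 0.8)) {
  if (inherits(draws, "posterior_draws")) {
    mat <- draws$draws; ids <- draws$area_ids
  } else {
    mat <- as.matrix(draws)
    ids <- colnames(mat)
    .assert(!is.null(ids), "draws matrix must have area ids as column names")
  }
  .assert(nrow(mat) >= 2, "need at least 2 retained draws")
  out <- lapply(seq_along(ids), function(k) {
    x <- mat[, k]
    p <- ppd(x, reference)
    c60 <- credible_interval(x, 60)
    c80 <- credible_interval(x, 80)
    data.frame(area_id = ids[k], point = point_estimate(x),
               ci60_lo = c60[1], ci60_hi = c60[2],
               ci80_lo = c80[1], ci80_hi = c80[2],
               ppd = p, v_conf = v_confidence(p),
               category = classify_difference(p, thresholds),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("area_summary", "data.frame"))
}
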