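# Atlas uncertainty encodings as renderable, testable specification objects:
# wave plot, V-plot, PPD-driven transparency choropleth styling, and grouped
# estimate overviews. All numbers live in the spec objects; rendering
# (render.R) is presentation-only.

# reversed ColorBrewer-style diverging blue-yellow-red ramp; the midpoint
# "#FFFFBF" is the pale neutral yellow used for the national average
.default_ramp <- c("#313695", "#4575B4", "#74ADD1", "#ABD9E9", "#E0F3F8",
                   "#FFFFBF", "#FEE090", "#FDAE61", "#F46D43", "#D73027",
                   "#A50026")

#' The neutral national-average color
#'
#' The pale yellow at the midpoint of the diverging ramp, used for a ratio
#' of exactly 1 and as the base color that uncertain areas fade toward.
#' @param anchors ramp anchor colors (odd count; middle one is returned).
#' @return Hex color string.
#' @export
average_color <- function(anchors = .default_ramp) {
  anchors[(length(anchors) + 1) / 2]
}

# position t in [0,1] on the diverging scale, piecewise-linear in log space
# and anchored so that estimate 1 sits exactly at t = 0.5 for any breakpoints
.color_position <- function(estimate, breakpoints) {
  lo <- breakpoints[1]; hi <- breakpoints[2]
  le <- log(estimate)
  t <- ifelse(le <= 0, 0.5 * (1 - pmin(1, le / log(lo))),
              0.5 + 0.5 * pmin(1, le / log(hi)))
  pmin(1, pmax(0, t))
}

#' Map a ratio-scale estimate to the diverging fill color
#'
#' Estimates are placed on the blue-yellow-red diverging ramp linearly in
#' log space (so the color gradient is consistent between break-points on
#' the ratio scale), anchored so an estimate of exactly 1 always maps to the
#' neutral pale yellow. Estimates at or below `breakpoints[1]` take the blue
#' end, at or above `breakpoints[2]` the red end.
#'
#' @param estimate positive ratio-scale estimate(s).
#' @param breakpoints `c(lo, hi)` with `0 < lo < 1 < hi`; default `c(0.5, 2)`
#'   is symmetric in log space, so `r` and `1/r` are equally saturated.
#' @param anchors ramp anchor hex colors, interpolated linearly in sRGB.
#' @return Hex color string(s).
#' @export
estimate_color <- function(estimate, breakpoints = c(0.5, 2),
                           anchors = .default_ramp) {
  .assert(is.numeric(estimate) && all(is.finite(estimate)) &&
          all(estimate > 0), "estimate must be positive")
  .assert(length(breakpoints) == 2 && breakpoints[1] > 0 &&
          breakpoints[1] < 1 && breakpoints[2] > 1,
          "breakpoints must satisfy 0 < lo < 1 < hi")
  t <- .color_position(estimate, breakpoints)
  m <- colorRamp(anchors, space = "rgb", interpolate = "linear")(t)
  rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

# alpha transfer function: c = 2|ppd - 0.5|, piecewise linear between c_lo
# and c_hi with floor alpha_min (> 0 so faded areas stay visible)
.alpha_of_ppd <- function(p, mapping) {
  c_lo <- mapping[1]; c_hi <- mapping[2]; alpha_min <- mapping[3]
  cc <- 2 * abs(p - 0.5)
  ifelse(cc <= c_lo, alpha_min,
         ifelse(cc >= c_hi, 1,
                alpha_min + (1 - alpha_min) * (cc - c_lo) / (c_hi - c_lo)))
}

# composite hex color over an opaque base (linear sRGB interpolation)
.blend <- function(fill, alpha, base) {
  f <- t(col2rgb(fill)); b <- t(col2rgb(base))
  if (nrow(b) == 1 && nrow(f) > 1) b <- b[rep(1, nrow(f)), , drop = FALSE]
  m <- f * alpha + b * (1 - alpha)
  rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

#' PPD-driven transparency styling
#'
#' Fades an area's fill toward the neutral average yellow according to how
#' uncertain its difference from the national average is. With confidence
#' `c = 2 * |ppd - 0.5|`, the opacity is `alpha_min` for `c <= c_lo`, 1 for
#' `c >= c_hi`, and linear in between; the rendered fill composites the
#' color over the pale-yellow base at that opacity. Transparency is on by
#' default; disabling it sets every `alpha` to 1.
#'
#' @param fill hex fill color(s), typically from [estimate_color].
#' @param p PPD value(s) in `[0, 1]`.
#' @param mapping `c(c_lo, c_hi, alpha_min)`; defaults `c(0.2, 0.6, 0.1)`.
#' @param enabled logical; `FALSE` reproduces the atlas's transparency-off
#'   toggle.
#' @param base the neutral base color faded toward.
#' @param area_id optional ids carried into the result.
#' @return Data frame of class `style_spec` with columns `area_id`, `fill`
#'   (the unfaded color), `alpha`, and `rendered` (fill composited over the
#'   base at `alpha`).
#' @export
apply_transparency <- function(fill, p, mapping = c(0.2, 0.6, 0.1),
                               enabled = TRUE, base = average_color(),
                               area_id = NULL) {
  .assert(.is_prob(p), "ppd must be in [0, 1]")
  .assert(length(mapping) == 3 && mapping[1] >= 0 &&
          mapping[1] < mapping[2] && mapping[2] <= 1 &&
          mapping[3] > 0 && mapping[3] < 1,
          "mapping must be (c_lo, c_hi, alpha_min) with 0 <= c_lo < c_hi <= 1, ",
          "alpha_min in (0, 1)")
  k <- max(length(fill), length(p))
  fill <- rep_len(fill, k); p <- rep_len(p, k)
  if (is.null(area_id)) area_id <- as.character(seq_len(k))
  alpha <- if (isTRUE(enabled)) .alpha_of_ppd(p, mapping) else rep(1, k)
  structure(
    data.frame(area_id = as.character(area_id), fill = fill, alpha = alpha,
               rendered = .blend(fill, alpha, base), stringsAsFactors = FALSE),
    class = c("style_spec", "data.frame"))
}

#' Per-area choropleth styles from an area summary
#'
#' Convenience wrapper: colors each area's point estimate with
#' [estimate_color] and applies the PPD transparency encoding.
#'
#' @param summaries an `area_summary` data frame ([summarize_all]).
#' @param breakpoints,anchors passed to [estimate_color].
#' @param mapping,enabled passed to [apply_transparency].
#' @return A `style_spec` data frame, one row per area.
#' @export
area_styles <- function(summaries, breakpoints = c(0.5, 2),
                        anchors = .default_ramp, mapping = c(0.2, 0.6, 0.1),
                        enabled = TRUE) {
  stopifnot(inherits(summaries, "area_summary"))
  fill <- estimate_color(summaries$point, breakpoints, anchors)
  apply_transparency(fill, summaries$ppd, mapping, enabled,
                     base = average_color(anchors),
                     area_id = summaries$area_id)
}

#' Wave-plot specification for one area
#'
#' The wave plot shows the empirical posterior density of the logarithm of
#' the ratio-scale measure (so the area under the curve is meaningful on a
#' linear axis) but relabels the x-axis with exponentiated, ratio-scale
#' values. A Gaussian kernel density estimate with Silverman's bandwidth is
#' evaluated on an even log-scale grid extending 3 bandwidths beyond the
#' draw range; the overlay glyph carries the posterior median and the 60%
#' and 80% intervals.
#'
#' @param draws positive posterior draws for one area (>= 50).
#' @param summary optional one-row `area_summary` slice for the area; if
#'   omitted, it is computed from the draws.
#' @param grid_size number of grid points.
#' @param ticks ratio-scale tick values; those outside the grid are clipped.
#' @param area_id id recorded in the spec.
#' @return Object of class `wave_spec`: `log_grid`, `density`, `ticks`
#'   (data frame `position`, `label`), `point`, `ci60`, `ci80`, `area_id`.
#' @export
wave_plot_spec <- function(draws, summary = NULL, grid_size = 256,
                           ticks = c(0.5, 0.75, 1, 4 / 3, 2),
                           area_id = "area") {
  .assert(length(draws) >= 50, "need at least 50 draws for a stable density")
  .assert(all(draws > 0), "draws must be positive")
  ld <- log(draws)
  bw <- bw.nrd0(ld)
  if (bw <= 0) bw <- max(1e-6, abs(mean(ld)) * 1e-3 + 1e-6)
  lo <- min(ld) - 3 * bw
  hi <- max(ld) + 3 * bw
  kde <- density(ld, bw = bw, kernel = "gaussian", from = lo, to = hi,
                 n = grid_size)
  keep <- log(ticks) >= lo & log(ticks) <= hi
  tick_pos <- log(ticks[keep])
  if (is.null(summary)) {
    m <- matrix(draws, ncol = 1, dimnames = list(NULL, area_id))
    summary <- summarize_all(m)
  }
  structure(list(
    area_id = area_id,
    log_grid = kde$x, density = kde$y,
    ticks = data.frame(position = tick_pos,
                       label = as.character(signif(exp(tick_pos), 3)),
                       stringsAsFactors = FALSE),
    point = summary$point[1],
    ci60 = c(summary$ci60_lo[1], summary$ci60_hi[1]),
    ci80 = c(summary$ci80_lo[1], summary$ci80_hi[1])),
    class = "wave_spec")
}

#' V-plot specification
#'
#' One point per area: the ratio-scale point estimate on the x-axis (drawn
#' on a log axis so departures above and below 1 are symmetric) and the
#' folded confidence `max(ppd, 1 - ppd)` on the y-axis. Areas most likely to
#' differ from the national average — in either direction — sit at the top
#' of the V; unlike the superseded S-plot there is no directional emphasis.
#'
#' @param summaries an `area_summary` data frame.
#' @param styles optional `style_spec` aligned by `area_id`.
#' @return Data frame of class `vplot_spec`: `area_id`, `x` (point
#'   estimate), `y` (folded confidence), plus `fill`/`alpha` when styles are
#'   given.
#' @export
v_plot_spec <- function(summaries, styles = NULL) {
  stopifnot(inherits(summaries, "area_summary"))
  out <- data.frame(area_id = summaries$area_id, x = summaries$point,
                    y = v_confidence(summaries$ppd),
                    stringsAsFactors = FALSE)
  if (!is.null(styles)) {
    .assert(identical(as.character(styles$area_id),
                      as.character(summaries$area_id)),
            "styles and summaries must align by area_id")
    out$fill <- styles$fill
    out$alpha <- styles$alpha
  }
  structure(out, class = c("vplot_spec", "data.frame"))
}

# class bin edges on the color-position scale t in [0,1]
.class_breaks <- function(n_classes) seq(0, 1, length.out = n_classes + 1)

#' Grouped estimate overviews
#'
#' Summarizes the per-area point estimates within groups (e.g. capital
#' cities, states, socioeconomic or remoteness categories) for side-by-side
#' barcode bars on a common axis. In `percentage`/`count` mode each group's
#' estimates are binned into the color classes of the diverging scale; in
#' `boxplot` mode each group gets the five-number summary of its member
#' estimates.
#'
#' @param summaries an `area_summary` data frame.
#' @param groups named character vector or list mapping every `area_id` to a
#'   group label.
#' @param mode `"percentage"`, `"count"` or `"boxplot"`.
#' @param breakpoints diverging-scale breakpoints (as in [estimate_color]).
#' @param n_classes number of color classes for the binned modes.
#' @param anchors ramp anchors for the class colors.
#' @return Object of class `overview_spec`: `groups` (ordered labels),
#'   `mode`, `classes` (class colors and estimate-scale edges, binned
#'   modes), `values` (matrix: group x class, or group x five-number
#'   summary), `axis` (shared x-range), `group_sizes`.
#' @export
overview_spec <- function(summaries, groups,
                          mode = c("percentage", "count", "boxplot"),
                          breakpoints = c(0.5, 2), n_classes = 5,
                          anchors = .default_ramp) {
  stopifnot(inherits(summaries, "area_summary"))
  mode <- match.arg(mode)
  g <- unlist(groups)
  missing_ids <- setdiff(summaries$area_id, names(g))
  .assert(length(missing_ids) == 0, "unassigned area(s): ",
          paste(head(missing_ids, 5), collapse = ", "))
  lab <- as.character(g[summaries$area_id])
  group_levels <- unique(as.character(g))
  est <- summaries$point
  sizes <- vapply(group_levels, function(gl) sum(lab == gl), numeric(1))
  axis <- range(est)
  if (mode == "boxplot") {
    vals <- t(vapply(group_levels, function(gl) {
      x <- est[lab == gl]
      if (length(x) == 0) rep(NA_real_, 5) else fivenum(x)
    }, numeric(5)))
    colnames(vals) <- c("min", "q1", "median", "q3", "max")
    classes <- NULL
  } else {
    brk <- .class_breaks(n_classes)
    t_est <- .color_position(est, breakpoints)
    bin <- pmin(n_classes, findInterval(t_est, brk, rightmost.closed = TRUE))
    counts <- t(vapply(group_levels, function(gl) {
      tabulate(bin[lab == gl], nbins = n_classes)
    }, numeric(n_classes)))
    vals <- if (mode == "count") counts else {
      sweep(counts, 1, pmax(1e-300, rowSums(counts)), "/") * 100
    }
    mid_t <- (brk[-1] + brk[-length(brk)]) / 2
    m <- colorRamp(anchors)(mid_t)
    classes <- data.frame(
      t_lo = brk[-length(brk)], t_hi = brk[-1],
      color = rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255),
      stringsAsFactors = FALSE)
    colnames(vals) <- paste0("class_", seq_len(n_classes))
  }
  rownames(vals) <- group_levels
  structure(list(groups = group_levels, mode = mode, classes = classes,
                 values = vals, axis = axis, group_sizes = sizes),
            class = "overview_spec")
}

#' Serialize a visualization spec to JSON
#'
#' All spec objects (wave, V-plot, styles, overview) serialize to JSON for
#' downstream consumption (e.g. a web front end).
#'
#' @param spec a `wave_spec`, `vplot_spec`, `style_spec` or `overview_spec`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
spec_to_json <- function(spec, path = NULL) {
  x <- unclass(spec)
  json <- jsonlite::toJSON(x, dataframe = "columns", digits = NA,
                           auto_unbox = TRUE, matrix = "rowmajor")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
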