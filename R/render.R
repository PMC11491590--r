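# Reference renderers for the spec objects. Rendering is presentation-only:
# every number shown comes from the spec object, so specs can be tested (and
# re-rendered, e.g. by a web front end) independently of these functions.

.save_plot <- function(p, file, width = 6, height = 4) {
  ext <- tolower(tools::file_ext(file))
  .assert(ext %in% c("png", "svg"), "output file must be .png or .svg")
  ggplot2::ggsave(file, plot = p, width = width, height = height, dpi = 120,
                  device = if (ext == "svg") grDevices::svg else "png")
  invisible(file)
}

#' Render a wave plot
#'
#' Filled posterior density of the log measure with the x-axis labeled in
#' ratio-scale units, overlaid with the posterior median and the 60%/80%
#' interval glyph.
#'
#' @param spec a `wave_spec` from [wave_plot_spec].
#' @param file output path (`.png` or `.svg`).
#' @return The file path, invisibly.
#' @export
render_wave_plot <- function(spec, file) {
  stopifnot(inherits(spec, "wave_spec"))
  df <- data.frame(x = spec$log_grid, y = spec$density)
  ymax <- max(df$y)
  band <- data.frame(
    lo = log(c(spec$ci80[1], spec$ci60[1])),
    hi = log(c(spec$ci80[2], spec$ci60[2])),
    h = c(0.03, 0.06) * ymax)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_area(fill = "#4575B4", alpha = 0.5) +
    ggplot2::geom_line(color = "#313695") +
    ggplot2::geom_segment(
      data = band, inherit.aes = FALSE,
      ggplot2::aes(x = lo, xend = hi, y = -h,
                   yend = -h),
      linewidth = c(1.5, 3), color = "#D73027", lineend = "butt") +
    ggplot2::geom_point(
      data = data.frame(x = log(spec$point), y = -0.045 * ymax),
      ggplot2::aes(x = x, y = y), shape = 18, size = 3) +
    ggplot2::scale_x_continuous(breaks = spec$ticks$position,
                                labels = spec$ticks$label) +
    ggplot2::labs(x = "ratio (national average = 1)", y = "posterior density",
                  title = spec$area_id) +
    ggplot2::theme_minimal()
  .save_plot(p, file)
}

#' Render a V-plot
#'
#' Scatter of point estimates (log axis) against folded confidence; the
#' dashed line marks the national average.
#'
#' @param spec a `vplot_spec` from [v_plot_spec].
#' @param file output path (`.png` or `.svg`).
#' @return The file path, invisibly.
#' @export
render_v_plot <- function(spec, file) {
  stopifnot(inherits(spec, "vplot_spec"))
  has_style <- !is.null(spec$fill)
  p <- ggplot2::ggplot(spec, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", color = "grey50")
  p <- if (has_style) {
    p + ggplot2::geom_point(color = spec$fill, alpha = spec$alpha, size = 2)
  } else {
    p + ggplot2::geom_point(size = 2, alpha = 0.8)
  }
  p <- p +
    ggplot2::scale_x_log10() +
    ggplot2::ylim(0.5, 1) +
    ggplot2::labs(x = "estimate (national average = 1)",
                  y = "confidence of difference") +
    ggplot2::theme_minimal()
  .save_plot(p, file)
}

#' Render a grouped estimate overview
#'
#' Barcode-style stacked bars (percentage/count modes) or box-and-whisker
#' summaries (boxplot mode), groups side by side on a common axis.
#'
#' @param spec an `overview_spec` from [overview_spec].
#' @param file output path (`.png` or `.svg`).
#' @return The file path, invisibly.
#' @export
render_overview <- function(spec, file) {
  stopifnot(inherits(spec, "overview_spec"))
  if (spec$mode == "boxplot") {
    df <- as.data.frame(spec$values)
    df$group <- factor(rownames(spec$values), levels = rev(spec$groups))
    p <- ggplot2::ggplot(df, ggplot2::aes(y = group)) +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = min, xmax = max), height = 0.2) +
      ggplot2::geom_rect(
        ggplot2::aes(xmin = q1, xmax = q3,
                     ymin = as.numeric(group) - 0.3,
                     ymax = as.numeric(group) + 0.3),
        fill = "#74ADD1", color = "grey30") +
      ggplot2::geom_segment(
        ggplot2::aes(x = median, xend = median,
                     y = as.numeric(group) - 0.3,
                     yend = as.numeric(group) + 0.3),
        linewidth = 1) +
      ggplot2::labs(x = "estimate", y = NULL)
  } else {
    long <- do.call(rbind, lapply(seq_along(spec$groups), function(i) {
      data.frame(group = spec$groups[i],
                 class = seq_len(ncol(spec$values)),
                 value = spec$values[i, ],
                 color = spec$classes$color, stringsAsFactors = FALSE)
    }))
    long$group <- factor(long$group, levels = rev(spec$groups))
    long$class <- factor(long$class)
    p <- ggplot2::ggplot(long,
                         ggplot2::aes(x = value, y = group, fill = class)) +
      ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE),
                        color = "white", linewidth = 0.2) +
      ggplot2::scale_fill_manual(values = spec$classes$color,
                                 guide = "none") +
      ggplot2::labs(x = if (spec$mode == "percentage") "% of areas"
                    else "number of areas", y = NULL)
  }
  .save_plot(p + ggplot2::theme_minimal(), file)
}

#' Render a transparency-encoded choropleth
#'
#' Draws styled polygons from a GeoJSON FeatureCollection; each area's fill
#' is the rendered (PPD-faded) color from its `style_spec` row.
#'
#' @param styles a `style_spec` data frame covering all drawn areas.
#' @param geojson GeoJSON FeatureCollection (path, string, or parsed list).
#' @param file output path (`.png` or `.svg`).
#' @param id_property feature property holding the area id.
#' @return The file path, invisibly.
#' @export
render_choropleth <- function(styles, geojson, file,
                              id_property = "area_id") {
  stopifnot(inherits(styles, "style_spec"))
  fc <- .parse_geojson(geojson)
  ids <- vapply(fc$features,
                function(f) as.character(f$properties[[id_property]]),
                character(1))
  missing_ids <- setdiff(styles$area_id, ids)
  .assert(length(missing_ids) == 0, "no polygon for styled area(s): ",
          paste(head(missing_ids, 5), collapse = ", "))
  rings <- lapply(fc$features, function(f) .geom_rings(f$geometry))
  df <- do.call(rbind, lapply(seq_along(ids), function(i) {
    do.call(rbind, lapply(seq_along(rings[[i]]), function(r) {
      m <- rings[[i]][[r]]
      data.frame(x = m[, 1], y = m[, 2], id = ids[i],
                 ring = paste(ids[i], r), stringsAsFactors = FALSE)
    }))
  }))
  fill <- setNames(styles$rendered, styles$area_id)[df$id]
  fill[is.na(fill)] <- "grey80"  # areas present in the map but unstyled
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                        group = ring)) +
    ggplot2::geom_polygon(fill = fill, color = "grey40", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  .save_plot(p, file, width = 6, height = 6)
}
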