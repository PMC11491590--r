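# CSV / JSON / GeoJSON readers and writers. Floats are written with 6
# significant digits for cross-platform diffability; readers reconstruct
# the package's objects, so write-then-read round-trips agree to that
# formatting precision.

.fmt <- function(x) {
  if (is.numeric(x) && !all(x == round(x))) formatC(x, digits = 6,
                                                    format = "g")
  else x
}

.write_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmt), stringsAsFactors = FALSE,
                       check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_columns <- function(df, cols, path) {
  missing_cols <- setdiff(cols, names(df))
  .assert(length(missing_cols) == 0, "file '", path,
          "' is missing column(s): ", paste(missing_cols, collapse = ", "))
}

#' Read / write an adjacency edge list
#'
#' CSV with header `area_id_1,area_id_2`, one undirected edge per row.
#'
#' @param path CSV file path.
#' @param area_ids ordered ids for the graph (for `read_edge_csv`); defaults
#'   to the ids appearing in the file, in order of first appearance.
#' @return `read_edge_csv`: a `region_graph`; `write_edge_csv`: the path.
#' @export
read_edge_csv <- function(path, area_ids = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .check_columns(df, c("area_id_1", "area_id_2"), path)
  if (is.null(area_ids)) area_ids <- unique(c(rbind(df$area_id_1,
                                                    df$area_id_2)))
  build_graph(cbind(df$area_id_1, df$area_id_2), area_ids)
}

#' @rdname read_edge_csv
#' @param graph a `region_graph` to write.
#' @export
write_edge_csv <- function(graph, path) {
  stopifnot(inherits(graph, "region_graph"))
  .write_csv(data.frame(area_id_1 = graph$area_ids[graph$edges[, 1]],
                        area_id_2 = graph$area_ids[graph$edges[, 2]],
                        stringsAsFactors = FALSE), path)
}

#' Read / write incidence data
#'
#' CSV with header `area_id,observed,expected`.
#' @param path CSV file path.
#' @return `read_incidence_csv`: an [incidence_data].
#' @export
read_incidence_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("area_id", "observed", "expected"), path)
  incidence_data(as.character(df$area_id), df$observed, df$expected)
}

#' @rdname read_incidence_csv
#' @param data an [incidence_data] to write.
#' @export
write_incidence_csv <- function(data, path) {
  stopifnot(inherits(data, "incidence_data"))
  .write_csv(data, path)
}

#' Read / write survival data
#'
#' CSV with header `area_id,interval,deaths,expected_deaths,person_time`.
#' @param path CSV file path.
#' @return `read_survival_csv`: a [survival_data].
#' @export
read_survival_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("area_id", "interval", "deaths", "expected_deaths",
                       "person_time"), path)
  survival_data(as.character(df$area_id), df$interval, df$deaths,
                df$expected_deaths, df$person_time)
}

#' @rdname read_survival_csv
#' @param data a [survival_data] to write.
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "survival_data"))
  .write_csv(data, path)
}

#' Persist posterior draws
#'
#' The draws matrix goes to CSV (area ids as columns, retained iterations as
#' rows) and the hyperparameter draws plus metadata to a JSON sidecar;
#' [read_draws] reconstructs the `posterior_draws` object.
#'
#' @param draws a `posterior_draws` object.
#' @param csv_path path for the draws CSV.
#' @param meta_path path for the JSON sidecar; default replaces the CSV
#'   extension with `.json`.
#' @return The CSV path, invisibly.
#' @export
write_draws <- function(draws, csv_path,
                        meta_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(draws, "posterior_draws"))
  .write_csv(as.data.frame(draws$draws, check.names = FALSE), csv_path)
  meta <- draws$meta
  meta$config <- unclass(meta$config)
  meta$priors <- unclass(meta$priors)
  payload <- list(area_ids = draws$area_ids,
                  hyper = lapply(draws$hyper, function(x)
                    as.numeric(formatC(x, digits = 6, format = "g"))),
                  meta = meta)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), meta_path)
  invisible(csv_path)
}

#' @rdname write_draws
#' @export
read_draws <- function(csv_path,
                       meta_path = sub("\\.csv$", ".json", csv_path)) {
  mat <- as.matrix(read.csv(csv_path, check.names = FALSE))
  side <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  .assert(identical(colnames(mat), as.character(side$area_ids)),
          "draws CSV columns do not match the sidecar area ids")
  meta <- side$meta
  if (!is.null(meta$config)) {
    cfg <- meta$config
    meta$config <- mcmc_config(cfg$n_iter, cfg$n_burn, cfg$thin, cfg$seed,
                               steps = as.list(cfg$steps),
                               adapt = isTRUE(cfg$adapt))
  }
  structure(list(area_ids = as.character(side$area_ids), draws = mat,
                 hyper = as.data.frame(side$hyper), meta = meta),
            class = "posterior_draws")
}

#' Read / write area summaries
#'
#' CSV with header
#' `area_id,point,ci60_lo,ci60_hi,ci80_lo,ci80_hi,ppd,v_conf,category`, one
#' row per area in deterministic (draws) order.
#'
#' @param path CSV file path.
#' @return `read_summary_csv`: an `area_summary` data frame.
#' @export
read_summary_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("area_id", "point", "ci60_lo", "ci60_hi", "ci80_lo",
                       "ci80_hi", "ppd", "v_conf", "category"), path)
  df$area_id <- as.character(df$area_id)
  structure(df, class = c("area_summary", "data.frame"))
}

#' @rdname read_summary_csv
#' @param summaries an `area_summary` to write.
#' @export
write_summary_csv <- function(summaries, path) {
  stopifnot(inherits(summaries, "area_summary"))
  .write_csv(summaries, path)
}

#' Write the truth record of a simulated scenario
#'
#' Sidecar CSV (`area_id,S,measure` plus constant columns for the generating
#' parameters) sufficient to compute coverage and recovery metrics.
#'
#' @param sim result of [simulate_incidence] or [simulate_survival].
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_truth_csv <- function(sim, path) {
  measure <- if (!is.null(sim$truth$sir)) sim$truth$sir else sim$truth$ehr
  df <- data.frame(area_id = sim$graph$area_ids, S = sim$truth$S,
                   measure = measure, rho = sim$truth$rho,
                   sigma2 = sim$truth$sigma2, stringsAsFactors = FALSE)
  if (!is.null(sim$truth$mu)) df$mu <- sim$truth$mu
  .write_csv(df, path)
}

#' Write a styled GeoJSON FeatureCollection
#'
#' Copies the input polygons and adds `fill`, `alpha` and `rendered`
#' properties per feature from a `style_spec`.
#'
#' @param styles a `style_spec` covering the features to style.
#' @param geojson input FeatureCollection (path, string or parsed list).
#' @param path output file.
#' @param id_property feature property holding the area id.
#' @return The path, invisibly.
#' @export
write_styled_geojson <- function(styles, geojson, path,
                                 id_property = "area_id") {
  stopifnot(inherits(styles, "style_spec"))
  fc <- .parse_geojson(geojson)
  lut <- split(styles, seq_len(nrow(styles)))
  names(lut) <- styles$area_id
  fc$features <- lapply(fc$features, function(f) {
    id <- as.character(f$properties[[id_property]])
    st <- lut[[id]]
    if (!is.null(st)) {
      f$properties$fill <- st$fill
      f$properties$alpha <- st$alpha
      f$properties$rendered <- st$rendered
    }
    f
  })
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
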