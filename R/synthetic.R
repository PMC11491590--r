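# Synthetic lattice scenarios with the statistical structure the models
# assume: a Leroux CAR spatial field on a rook-adjacency grid, heterogeneous
# expected counts, and Poisson-generated observations. Truth records carry
# everything needed for parameter-recovery and coverage studies.

#' Simulation scenario configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's simulation checks: a 10x10 lattice with strong spatial
#' dependence (`rho = 0.8`), moderate spatial variance (`sigma2 = 0.25`),
#' national-average intercept (`mu = 0`), and registry-scale expected counts
#' (`E_i ~ Uniform(50, 200)`). Survival settings emulate five annual
#' follow-up intervals with a baseline excess hazard of 0.05 and a
#' background hazard of 0.02 per person-year, 500 person-years per
#' area-interval.
#'
#' @param nrows,ncols lattice dimensions (`nrows * ncols >= 4`).
#' @param rho spatial mixing in `[0, 1)`.
#' @param sigma2 spatial variance, `> 0`.
#' @param mu log-scale intercept of the incidence model.
#' @param E_range range of the uniform expected counts, min `> 0`.
#' @param n_intervals number of survival follow-up intervals.
#' @param baseline_lambda baseline excess hazard per interval
#'   (deaths per person-year); recycled to `n_intervals`.
#' @param background_rate background mortality hazard (per person-year).
#' @param person_time person-time at risk per area-interval.
#' @param seed integer RNG seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(nrows = 10, ncols = 10, rho = 0.8, sigma2 = 0.25,
                            mu = 0, E_range = c(50, 200), n_intervals = 5,
                            baseline_lambda = 0.05, background_rate = 0.02,
                            person_time = 500, seed = 1) {
  .assert(nrows >= 1 && ncols >= 1 && nrows * ncols >= 4,
          "lattice must have at least 4 areas")
  .assert(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  .assert(sigma2 > 0, "sigma2 must be positive")
  .assert(length(E_range) == 2 && E_range[1] > 0 && E_range[1] <= E_range[2],
          "E_range must be (min, max) with min > 0")
  .assert(n_intervals >= 1, "need at least one interval")
  .assert(all(baseline_lambda >= 0) && background_rate >= 0 &&
          person_time > 0, "rates must be non-negative, person_time positive")
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 rho = rho, sigma2 = sigma2, mu = mu, E_range = E_range,
                 n_intervals = as.integer(n_intervals),
                 baseline_lambda = rep_len(baseline_lambda, n_intervals),
                 background_rate = background_rate,
                 person_time = person_time, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Rook-adjacency lattice graph
#'
#' Regular `nrows x ncols` grid with area ids `"r{i}c{j}"`; horizontally and
#' vertically adjacent cells are neighbors, giving
#' `nrows*(ncols-1) + ncols*(nrows-1)` edges.
#'
#' @param nrows,ncols positive lattice dimensions.
#' @return A `region_graph`.
#' @export
make_lattice <- function(nrows, ncols) {
  .assert(nrows >= 1 && ncols >= 1 && nrows == round(nrows) &&
          ncols == round(ncols), "dimensions must be positive integers")
  id <- function(i, j) paste0("r", i, "c", j)
  ids <- as.vector(t(outer(seq_len(nrows), seq_len(ncols), id)))
  from <- character(0); to <- character(0)
  for (i in seq_len(nrows)) {
    for (j in seq_len(ncols)) {
      if (j < ncols) { from <- c(from, id(i, j)); to <- c(to, id(i, j + 1)) }
      if (i < nrows) { from <- c(from, id(i, j)); to <- c(to, id(i + 1, j)) }
    }
  }
  build_graph(if (length(from)) cbind(from, to) else NULL, ids)
}

#' Draw spatial fields from the Leroux CAR prior
#'
#' Exact sampling from `N(0, Q(rho, sigma2)^{-1})` via a Cholesky
#' factorization of the dense precision; intended for fixture-scale graphs
#' (`n <= 2500`).
#'
#' @param graph a `region_graph` with at most 2500 areas.
#' @param rho mixing parameter in `[0, 1)` (`rho = 1` is improper).
#' @param sigma2 spatial variance.
#' @param seed optional integer seed; when given, the draw is deterministic.
#' @param n_draws number of independent fields.
#' @return A numeric vector (one draw) or an `n_draws x n` matrix.
#' @export
sample_leroux_field <- function(graph, rho, sigma2, seed = NULL,
                                n_draws = 1) {
  stopifnot(inherits(graph, "region_graph"))
  .assert(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  .assert(graph$n <= 2500,
          "dense factorization sampling is capped at 2500 areas")
  if (!is.null(seed)) set.seed(seed)
  Q <- as.matrix(leroux_precision(graph, rho, sigma2))
  R <- chol(Q)  # Q = R'R  =>  S = R^{-1} z has covariance Q^{-1}
  z <- matrix(rnorm(graph$n * n_draws), graph$n, n_draws)
  S <- backsolve(R, z)
  if (n_draws == 1) {
    setNames(as.vector(S), graph$area_ids)
  } else {
    t(structure(S, dimnames = list(graph$area_ids, NULL)))
  }
}

#' Simulate an incidence dataset from the model family
#'
#' Draws a Leroux CAR spatial field on the scenario lattice, uniform
#' expected counts, and Poisson observed counts
#' `y_i ~ Poisson(E_i * exp(mu + S_i))`. The truth record stores the field,
#' the true `SIR_i = exp(mu + S_i)`, and the generating parameters.
#'
#' @param config a [scenario_config].
#' @return List with `graph` (a `region_graph`), `data` (an
#'   [incidence_data]) and `truth` (list: `S`, `sir`, `rho`, `sigma2`,
#'   `mu`).
#' @export
simulate_incidence <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  graph <- make_lattice(config$nrows, config$ncols)
  set.seed(config$seed)
  E <- runif(graph$n, config$E_range[1], config$E_range[2])
  S <- sample_leroux_field(graph, config$rho, config$sigma2)
  sir <- exp(config$mu + S)
  y <- rpois(graph$n, E * sir)
  list(graph = graph,
       data = incidence_data(graph$area_ids, y, E),
       truth = list(S = S, sir = sir, rho = config$rho,
                    sigma2 = config$sigma2, mu = config$mu))
}

#' Simulate a survival (excess mortality) dataset
#'
#' Fixed person-time per area-interval, background deaths
#' `e_ij = background_rate * t_ij`, and observed deaths
#' `d_ij ~ Poisson(e_ij + t_ij * lambda_j * exp(S_i))`. The truth record
#' stores `EHR_i = exp(S_i)`.
#'
#' @param config a [scenario_config].
#' @return List with `graph`, `data` (a [survival_data]) and `truth`
#'   (list: `S`, `ehr`, `lambda`, `rho`, `sigma2`).
#' @export
simulate_survival <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  graph <- make_lattice(config$nrows, config$ncols)
  set.seed(config$seed + 1L)
  S <- sample_leroux_field(graph, config$rho, config$sigma2)
  ehr <- exp(S)
  J <- config$n_intervals
  grid <- expand.grid(interval = seq_len(J), area = seq_len(graph$n))
  t_ij <- rep(config$person_time, nrow(grid))
  e_ij <- config$background_rate * t_ij
  lam <- config$baseline_lambda[grid$interval]
  d_ij <- rpois(nrow(grid), e_ij + t_ij * lam * ehr[grid$area])
  list(graph = graph,
       data = survival_data(graph$area_ids[grid$area], grid$interval, d_ij,
                            e_ij, t_ij),
       truth = list(S = S, ehr = ehr, lambda = config$baseline_lambda,
                    rho = config$rho, sigma2 = config$sigma2))
}

#' GeoJSON of unit squares for a lattice graph
#'
#' Writes (or returns) a FeatureCollection of unit-square polygons for the
#' areas of a [make_lattice] grid, for end-to-end choropleth tests.
#'
#' @param nrows,ncols lattice dimensions (must match the graph in use).
#' @param path optional output file.
#' @param id_property property name for the area id.
#' @return Parsed FeatureCollection (list), invisibly when written to file.
#' @export
lattice_geojson <- function(nrows, ncols, path = NULL,
                            id_property = "area_id") {
  features <- list()
  for (i in seq_len(nrows)) {
    for (j in seq_len(ncols)) {
      x0 <- j - 1; y0 <- nrows - i  # row 1 at the top
      ring <- list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                   c(x0, y0 + 1), c(x0, y0))
      props <- list()
      props[[id_property]] <- paste0("r", i, "c", j)
      features[[length(features) + 1]] <- list(
        type = "Feature", properties = props,
        geometry = list(type = "Polygon", coordinates = list(ring)))
    }
  }
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
    return(invisible(fc))
  }
  fc
}
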