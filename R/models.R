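#' Per-area incidence data (observed and expected counts)
#'
#' Container for the inputs of the SIR model: observed case counts `y_i` and
#' externally age-standardized expected counts `E_i` per area. The model is
#' `y_i ~ Poisson(E_i * exp(mu + S_i))`, so the area-level standardized
#' incidence ratio is `SIR_i = exp(mu + S_i)` and a value of 1 is the
#' national average.
#'
#' @param area_ids character vector of unique area ids.
#' @param observed non-negative integer case counts.
#' @param expected positive expected counts.
#' @return A data frame of class `incidence_data` with columns `area_id`,
#'   `observed`, `expected`.
#' @export
incidence_data <- function(area_ids, observed, expected) {
  .assert(is.character(area_ids) && !anyDuplicated(area_ids),
          "area_ids must be unique character ids")
  .assert(length(observed) == length(area_ids) &&
          length(expected) == length(area_ids),
          "observed/expected length must match area_ids")
  .assert(.is_count(observed), "observed must be non-negative integers")
  .assert(is.numeric(expected) && all(is.finite(expected)) && all(expected > 0),
          "expected counts must be positive")
  structure(
    data.frame(area_id = area_ids, observed = as.numeric(observed),
               expected = as.numeric(expected), stringsAsFactors = FALSE),
    class = c("incidence_data", "data.frame"))
}

#' Per-area, per-interval survival (excess mortality) data
#'
#' Container for the excess-hazard model inputs: for area `i` and follow-up
#' interval `j`, the observed deaths `d_ij`, the expected background deaths
#' `e_ij` from population life tables, and the person-time at risk `t_ij`.
#' The model is `d_ij ~ Poisson(e_ij + t_ij * lambda_j * exp(S_i))` with
#' piecewise-constant baseline excess hazard `lambda_j`; the excess hazard
#' ratio is `EHR_i = exp(S_i)` and 1 is the national average.
#' Every area must carry every interval (a complete grid).
#'
#' @param area_id,interval,deaths,expected_deaths,person_time parallel
#'   vectors, one entry per area-interval cell.
#' @return A data frame of class `survival_data`.
#' @export
survival_data <- function(area_id, interval, deaths, expected_deaths,
                          person_time) {
  k <- length(area_id)
  .assert(all(lengths(list(interval, deaths, expected_deaths,
                           person_time)) == k),
          "all columns must have the same length")
  .assert(.is_count(deaths), "deaths must be non-negative integers")
  .assert(is.numeric(expected_deaths) && all(expected_deaths >= 0),
          "expected_deaths must be non-negative")
  .assert(is.numeric(person_time) && all(person_time > 0),
          "person_time must be positive")
  d <- data.frame(area_id = as.character(area_id),
                  interval = as.integer(interval),
                  deaths = as.numeric(deaths),
                  expected_deaths = as.numeric(expected_deaths),
                  person_time = as.numeric(person_time),
                  stringsAsFactors = FALSE)
  .assert(!anyDuplicated(d[c("area_id", "interval")]),
          "duplicate area/interval cells")
  tab <- table(d$area_id)
  .assert(length(unique(tab)) == 1 &&
          all(table(d$interval) == length(unique(d$area_id))),
          "survival data must form a complete area x interval grid")
  structure(d, class = c("survival_data", "data.frame"))
}

# survival long data -> list of n x J matrices in a given area order
.survival_matrices <- function(data, area_ids = NULL) {
  stopifnot(inherits(data, "survival_data"))
  if (is.null(area_ids)) area_ids <- unique(data$area_id)
  intervals <- sort(unique(data$interval))
  shape <- function(col) {
    m <- matrix(NA_real_, length(area_ids), length(intervals),
                dimnames = list(area_ids, intervals))
    m[cbind(match(data$area_id, area_ids), match(data$interval, intervals))] <-
      data[[col]]
    .assert(!anyNA(m), "survival data does not cover all listed areas")
    m
  }
  list(d = shape("deaths"), e = shape("expected_deaths"),
       t = shape("person_time"), intervals = intervals, area_ids = area_ids)
}

#' Poisson log-likelihood of the incidence model
#'
#' `sum_i log Poisson(y_i; E_i * exp(mu + S_i))`, including the `log(y_i!)`
#' normalizing terms so values are comparable across implementations.
#'
#' @param data an [incidence_data] object.
#' @param mu global intercept on the log-ratio scale.
#' @param S spatial random effect vector, one value per area in data order.
#' @return The log-likelihood (scalar).
#' @export
incidence_loglik <- function(data, mu, S) {
  stopifnot(inherits(data, "incidence_data"))
  .assert(length(S) == nrow(data), "length(S) must match the number of areas")
  sum(dpois(data$observed, data$expected * exp(mu + S), log = TRUE))
}

#' Poisson log-likelihood of the piecewise excess-hazard model
#'
#' `sum_ij log Poisson(d_ij; e_ij + t_ij * lambda_j * exp(S_i))`. A cell with
#' zero mean but positive deaths makes the likelihood `-Inf`; this is
#' returned as a value flagged via `attr(, "flagged")`, not an error.
#'
#' @param data a [survival_data] object.
#' @param lambda positive baseline excess hazard per follow-up interval
#'   (in interval order).
#' @param S spatial random effect vector, one per area (in order of first
#'   appearance in `data`).
#' @return The log-likelihood, possibly `-Inf` with attribute `flagged`.
#' @export
excess_hazard_loglik <- function(data, lambda, S) {
  m <- .survival_matrices(data)
  .assert(length(lambda) == length(m$intervals),
          "lambda must have one value per interval")
  .assert(all(lambda > 0), "lambda must be positive")
  .assert(length(S) == length(m$area_ids),
          "length(S) must match the number of areas")
  mean_mat <- m$e + m$t * matrix(lambda, nrow(m$d), ncol(m$d), byrow = TRUE) *
    exp(S)
  ll <- sum(dpois(m$d, mean_mat, log = TRUE))
  if (!is.finite(ll) && any(mean_mat == 0 & m$d > 0)) {
    attr(ll, "flagged") <- "zero-mean cell with positive deaths"
  }
  ll
}

#' Hyperprior configuration
#'
#' Weakly informative proper priors, standard in CAR disease mapping:
#' `sigma ~ half-Normal(0, sigma_sd^2)` on the spatial standard deviation,
#' `rho ~ Uniform(0, 1)`, and `Normal(0, mu_sd^2)` on the intercept `mu`
#' (incidence) or each `log lambda_j` (survival).
#'
#' @param mu_sd prior standard deviation of `mu` and `log lambda_j`.
#' @param sigma_sd scale of the half-Normal prior on `sigma`.
#' @return A list of class `car_priors`.
#' @export
car_priors <- function(mu_sd = 10, sigma_sd = 1) {
  .assert(mu_sd > 0 && sigma_sd > 0, "prior scales must be positive")
  structure(list(mu_sd = mu_sd, sigma_sd = sigma_sd), class = "car_priors")
}

# log density of the hyperpriors at (mu or loglambda, sigma2, rho)
.log_hyperprior <- function(coefs, sigma2, rho, priors) {
  sigma <- sqrt(sigma2)
  # half-normal on sigma: sqrt(2/pi)/s * exp(-sigma^2/(2 s^2)), sigma > 0
  lp_sigma <- log(2) + dnorm(sigma, 0, priors$sigma_sd, log = TRUE)
  lp_rho <- ifelse(rho >= 0 && rho < 1, 0, -Inf)  # Uniform(0,1)
  sum(dnorm(coefs, 0, priors$mu_sd, log = TRUE)) + lp_sigma + lp_rho
}

#' Joint log-posterior of the spatial model
#'
#' Likelihood plus the Leroux CAR Gaussian prior on `S` (with precision
#' [leroux_precision]) plus the hyperprior densities from [car_priors].
#' All normalizing constants that depend only on `(graph, priors)` are
#' included, so the value is an absolute log-density up to the usual
#' dominating-measure convention (densities of `sigma2` and `rho` taken on
#' their natural scales).
#'
#' @param params list with elements `S`, `rho`, `sigma2`, and `mu`
#'   (incidence) or `lambda` (survival).
#' @param data an [incidence_data] or [survival_data] object.
#' @param graph the `region_graph` over the same areas (same order).
#' @param priors a [car_priors] object.
#' @return The joint log-posterior density (scalar).
#' @export
log_posterior <- function(params, data, graph, priors = car_priors()) {
  stopifnot(inherits(graph, "region_graph"))
  S <- params$S
  .assert(length(S) == graph$n, "length(S) must equal the number of areas")
  if (inherits(data, "incidence_data")) {
    .assert(nrow(data) == graph$n, "data/graph dimension mismatch")
    ll <- incidence_loglik(data, params$mu, S)
    coefs <- params$mu
  } else if (inherits(data, "survival_data")) {
    .assert(length(unique(data$area_id)) == graph$n,
            "data/graph dimension mismatch")
    ll <- excess_hazard_loglik(data, params$lambda, S)
    coefs <- log(params$lambda)
  } else {
    stop("data must be incidence_data or survival_data", call. = FALSE)
  }
  Q <- leroux_precision(graph, params$rho, params$sigma2)
  ld <- as.numeric(Matrix::determinant(Q, logarithm = TRUE)$modulus)
  lp_S <- 0.5 * ld - 0.5 * as.numeric(S %*% (Q %*% S)) -
    0.5 * graph$n * log(2 * pi)
  as.numeric(ll) + lp_S +
    .log_hyperprior(coefs, params$sigma2, params$rho, priors)
}
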