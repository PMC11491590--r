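#' MCMC sampler configuration
#'
#' Defaults (60 000 iterations, 20 000 burn-in, thin 20, so 2000 retained
#' draws) give stable desk-scale summaries; shorter chains are adequate for
#' simulation studies. Step sizes are starting values for the random-walk
#' proposals; with `adapt = TRUE` they are tuned in batches during burn-in
#' (target acceptance 0.44) and frozen afterwards.
#'
#' @param n_iter total iterations.
#' @param n_burn burn-in iterations (`< n_iter`).
#' @param thin thinning stride (`>= 1`).
#' @param seed integer RNG seed; the chain is fully deterministic given the
#'   seed and inputs.
#' @param steps named list of initial proposal scales: `S`, `mu`,
#'   `loglambda`, `log_sigma2`, `logit_rho`.
#' @param adapt adapt step sizes during burn-in.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 60000, n_burn = 20000, thin = 20, seed = 1,
                        steps = list(), adapt = TRUE) {
  .assert(n_iter >= 1 && n_burn >= 0 && n_burn < n_iter,
          "need 0 <= n_burn < n_iter")
  .assert(thin >= 1 && thin == round(thin), "thin must be a positive integer")
  defaults <- list(S = 0.3, mu = 0.05, loglambda = 0.1,
                   log_sigma2 = 0.5, logit_rho = 0.7)
  defaults[names(steps)] <- steps
  n_keep <- floor((n_iter - n_burn) / thin)
  if (n_keep < 100) {
    warning("only ", n_keep, " retained draws; summaries need >= 100",
            call. = FALSE)
  }
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 steps = defaults, adapt = isTRUE(adapt), n_keep = n_keep),
            class = "mcmc_config")
}

# neighbor list (1-based) from a region_graph
.neighbor_list <- function(graph) {
  nb <- vector("list", graph$n)
  for (i in seq_len(graph$n)) nb[[i]] <- integer(0)
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Fit a Leroux CAR smoothing model by Metropolis-within-Gibbs MCMC
#'
#' Samples the joint posterior of the spatial effects, intercept (or interval
#' baselines), spatial variance `sigma2` and mixing parameter `rho`, and
#' returns the retained draws of the ratio-scale measure per area:
#' `SIR_i = exp(mu + S_i)` for the incidence model, `EHR_i = exp(S_i)` for
#' the survival model. Initialization is moment-based:
#' `mu = log(sum(y)/sum(E))`, `S = 0`, `rho = 0.5`, `sigma2 = 0.1`,
#' `lambda_j = max(1e-6, (sum(d) - sum(e))/sum(t))`.
#'
#' @param model `"incidence"` or `"survival"`.
#' @param data an [incidence_data] or [survival_data] object; area order must
#'   match `graph$area_ids`.
#' @param graph the `region_graph` defining the CAR prior.
#' @param priors a [car_priors] object.
#' @param config an [mcmc_config] object.
#' @param fix optional named list fixing hyperparameters instead of sampling
#'   them: any of `rho`, `sigma2` (e.g. `fix = list(rho = 0, sigma2 = 100)`).
#' @param prior_only if `TRUE` the likelihood is switched off and the chain
#'   samples the Leroux prior (the intercept/baselines stay at their initial
#'   values); used for prior-recovery checks.
#' @return An object of class `posterior_draws`: list with `area_ids`,
#'   `draws` (matrix, retained iterations x areas, ratio scale), `hyper`
#'   (data frame of `rho`, `sigma2` and `mu` or `lambda_j` per retained
#'   iteration), and `meta` (config, acceptance rates, warnings).
#' @export
run_chain <- function(model = c("incidence", "survival"), data, graph,
                      priors = car_priors(), config = mcmc_config(),
                      fix = list(), prior_only = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(graph, "region_graph"), inherits(config, "mcmc_config"))
  stopifnot(inherits(priors, "car_priors"))
  .assert(all(names(fix) %in% c("rho", "sigma2")),
          "fix may only contain rho and/or sigma2")

  if (model == "incidence") {
    .assert(inherits(data, "incidence_data"), "data must be incidence_data")
    .assert(identical(data$area_id, graph$area_ids),
            "data areas must match graph area_ids (same order)")
    y <- data$observed; E <- data$expected
    dmat <- emat <- tmat <- matrix(0, 1, 1)
    mu0 <- log(sum(y) / sum(E))
    if (!is.finite(mu0)) mu0 <- 0
    loglam0 <- numeric(0)
    intervals <- integer(0)
  } else {
    .assert(inherits(data, "survival_data"), "data must be survival_data")
    sm <- .survival_matrices(data, graph$area_ids)
    dmat <- sm$d; emat <- sm$e; tmat <- sm$t; intervals <- sm$intervals
    y <- E <- numeric(0)
    lam0 <- max(1e-6, (sum(dmat) - sum(emat)) / sum(tmat))
    loglam0 <- rep(log(lam0), length(intervals))
    mu0 <- 0
  }

  rho0 <- if (!is.null(fix$rho)) fix$rho else 0.5
  sigma20 <- if (!is.null(fix$sigma2)) fix$sigma2 else 0.1
  .assert(rho0 >= 0 && rho0 < 1, "rho must be in [0, 1)")
  .assert(sigma20 > 0, "sigma2 must be positive")

  R_struct <- leroux_precision(graph, rho = 1, unscaled = TRUE)  # D - W
  eig <- eigen(as.matrix(R_struct), symmetric = TRUE,
               only.values = TRUE)$values
  eig <- pmax(eig, 0)

  edges <- graph$edges
  if (nrow(edges) == 0) edges <- matrix(integer(0), ncol = 2)

  set.seed(config$seed)
  res <- car_chain_cpp(
    model = if (model == "incidence") 0L else 1L,
    y = as.numeric(y), E = as.numeric(E),
    dmat = dmat, emat = emat, tmat = tmat,
    nbrs = .neighbor_list(graph), edges = edges, eig = eig,
    n_iter = config$n_iter, n_burn = config$n_burn, thin = config$thin,
    mu = mu0, S_init = rep(0, graph$n),
    rho = rho0, sigma2 = sigma20, loglam_init = loglam0,
    sample_rho = is.null(fix$rho), sample_sigma2 = is.null(fix$sigma2),
    prior_only = isTRUE(prior_only),
    step_S0 = config$steps$S, step_mu0 = config$steps$mu,
    step_lrho0 = config$steps$logit_rho, step_lsig0 = config$steps$log_sigma2,
    step_llam0 = config$steps$loglambda,
    adapt = config$adapt,
    pr_mu_sd = priors$mu_sd, pr_sigma_sd = priors$sigma_sd)

  draws <- res$draws
  colnames(draws) <- graph$area_ids
  hyper <- as.data.frame(res$hyper)
  names(hyper) <- c("rho", "sigma2",
                    if (model == "incidence") "mu"
                    else paste0("lambda_", intervals))
  acc <- res$accept
  warn <- character(0)
  live <- acc[!is.na(acc)]
  bad <- live[live < 0.05 | live > 0.95]
  if (length(bad)) {
    warn <- paste0("acceptance rate outside [0.05, 0.95] for block(s): ",
                   paste(names(bad), collapse = ", "))
  }
  structure(list(
    area_ids = graph$area_ids, draws = draws, hyper = hyper,
    meta = list(model = model, config = config, priors = priors, fix = fix,
                prior_only = isTRUE(prior_only),
                accept = as.list(acc), warnings = warn)),
    class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", nrow(x$draws), "retained draws x",
      ncol(x$draws), "areas (", x$meta$model, "model )\n")
  acc <- unlist(x$meta$accept)
  cat("acceptance:", paste(names(acc), round(acc, 3), collapse = ", "), "\n")
  for (w in x$meta$warnings) cat("warning:", w, "\n")
  invisible(x)
}

# effective sample size via Geyer's initial positive sequence on the ACF
.ess <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 1, max(50, floor(10 * log10(n))) * 5)
  rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE)$acf)[-1]
  # pair sums rho_{2k-1} + rho_{2k}; truncate at the first negative pair
  tau <- 1
  k <- 1
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1 <= length(rho)) rho[k + 1] else 0
    if (pair < 0) break
    tau <- tau + 2 * rho[k] + if (k + 1 <= length(rho)) 2 * rho[k + 1] else 0
    k <- k + 2
  }
  min(n, n / max(tau, .Machine$double.eps))
}

# split-chain potential scale reduction factor (two halves of one chain)
.split_rhat <- function(x) {
  n2 <- floor(length(x) / 2)
  a <- x[seq_len(n2)]
  b <- x[seq(length(x) - n2 + 1, length(x))]
  W <- (var(a) + var(b)) / 2
  if (W == 0) return(NA_real_)
  mu_all <- (mean(a) + mean(b)) / 2
  B <- n2 * ((mean(a) - mu_all)^2 + (mean(b) - mu_all)^2)
  max(1, sqrt(((n2 - 1) / n2 * W + B / n2) / W))
}

#' Per-area convergence diagnostics
#'
#' Effective sample size (initial-positive-sequence estimator on the
#' autocorrelation function) and a split-chain potential-scale-reduction
#' diagnostic, computed on the log of the ratio-scale draws. A constant
#' chain has undefined diagnostics, reported as `NA` with `flagged = TRUE`.
#'
#' @param draws a `posterior_draws` object with at least 200 retained draws.
#' @return Data frame: `area_id`, `ess`, `rhat`, `flagged`.
#' @export
convergence_report <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  .assert(nrow(draws$draws) >= 200,
          "need at least 200 retained draws for diagnostics")
  ld <- log(draws$draws)
  ess <- apply(ld, 2, .ess)
  rhat <- apply(ld, 2, .split_rhat)
  data.frame(area_id = draws$area_ids, ess = ess, rhat = rhat,
             flagged = is.na(ess) | is.na(rhat), row.names = NULL,
             stringsAsFactors = FALSE)
}
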