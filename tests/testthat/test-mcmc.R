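test_that("chains are deterministic given the seed", {
  sim <- simulate_incidence(scenario_config(nrows = 3, ncols = 3, seed = 4))
  cfg <- mcmc_config(3000, 1000, 10, seed = 9)
  f1 <- run_chain("incidence", sim$data, sim$graph, config = cfg)
  f2 <- run_chain("incidence", sim$data, sim$graph, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$hyper, f2$hyper)
  f3 <- run_chain("incidence", sim$data, sim$graph,
                  config = mcmc_config(3000, 1000, 10, seed = 10))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("configuration invariants are enforced", {
  expect_error(mcmc_config(n_iter = 100, n_burn = 100), "n_burn")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_warning(mcmc_config(n_iter = 300, n_burn = 100, thin = 10),
                 "retained")
})

test_that("draws are positive, ordered by area, with acceptance in meta", {
  sim <- simulate_incidence(scenario_config(nrows = 3, ncols = 3, seed = 4))
  fit <- run_chain("incidence", sim$data, sim$graph,
                   config = mcmc_config(4000, 2000, 10, seed = 2))
  expect_equal(nrow(fit$draws), 200)  # floor((n_iter - n_burn)/thin)
  expect_identical(colnames(fit$draws), sim$graph$area_ids)
  expect_true(all(fit$draws > 0))
  acc <- unlist(fit$meta$accept)
  expect_true(all(acc > 0 & acc < 1))
})

test_that("single-area fit matches the conjugate Gamma-Poisson oracle", {
  # y = 5, E = 1, diffuse prior on mu, spatial prior switched off
  # (rho = 0 fixed, sigma2 fixed large): exp(mu + S) has an effectively
  # flat prior on the log scale, so the posterior is ~ Gamma(5, 1), mean 5.
  g1 <- build_graph(NULL, "A")
  fit <- run_chain("incidence", incidence_data("A", 5L, 1), g1,
                   config = mcmc_config(60000, 10000, 10, seed = 3),
                   fix = list(rho = 0, sigma2 = 100))
  expect_equal(mean(fit$draws), 5, tolerance = 0.05)
})

test_that("prior-only chains recover the Leroux prior on a 4x4 lattice", {
  g <- make_lattice(4, 4)
  dummy <- incidence_data(g$area_ids, rep(1L, 16), rep(1, 16))
  fit <- run_chain("incidence", dummy, g,
                   config = mcmc_config(42000, 2000, 8, seed = 7),
                   fix = list(rho = 0.8, sigma2 = 0.25), prior_only = TRUE)
  S <- log(fit$draws)  # mu fixed at log(sum y / sum E) = 0 in prior-only mode
  v_true <- diag(solve(as.matrix(leroux_precision(g, 0.8, 0.25))))
  expect_equal(unname(apply(S, 2, var)), unname(v_true), tolerance = 0.1)
  expect_lt(max(abs(colMeans(S))), 0.05)
})

test_that("posterior medians approach y/E when expected counts are large", {
  sim <- simulate_incidence(scenario_config(nrows = 3, ncols = 3,
                                            E_range = c(1e4, 1e4), seed = 6))
  fit <- run_chain("incidence", sim$data, sim$graph,
                   config = mcmc_config(8000, 3000, 5, seed = 8))
  med <- apply(fit$draws, 2, median)
  raw <- sim$data$observed / sim$data$expected
  expect_true(all(abs(med - raw) / raw < 0.05))
})

test_that("survival fits recover area EHRs on a small lattice", {
  sim <- simulate_survival(scenario_config(nrows = 3, ncols = 3,
                                           person_time = 5000, seed = 12))
  fit <- run_chain("survival", sim$data, sim$graph,
                   config = mcmc_config(8000, 3000, 5, seed = 13))
  med <- apply(fit$draws, 2, median)
  expect_gt(cor(med, sim$truth$ehr), 0.9)
  expect_true(all(c("rho", "sigma2", "lambda_1") %in% names(fit$hyper)))
})

test_that("initialization failures raise an informative error", {
  g <- build_graph(NULL, "A")
  d <- survival_data("A", 1L, 5L, 0, 1)
  # background 0 and tiny person-time x lambda: the sampler still
  # initializes (lambda > 0), but a zero-mean cell with deaths cannot:
  # construct it by zero expected background and zero excess is impossible
  # through validators, so check the config error path instead
  expect_error(run_chain("incidence", incidence_data("A", 1L, 1), g,
                         config = mcmc_config(100, 200, 1)), "n_burn")
  expect_error(run_chain("incidence", incidence_data("A", 1L, 1), g,
                         fix = list(rho = 1)), "rho")
})

test_that("effective sample size tracks independence and AR(1) theory", {
  set.seed(31)
  n <- 4000
  iid <- fake_draws(matrix(exp(rnorm(n * 2)), n, 2))
  rep_iid <- convergence_report(iid)
  expect_true(all(rep_iid$ess > 0.8 * n & rep_iid$ess <= n))
  expect_true(all(rep_iid$rhat < 1.05))

  # AR(1) with coefficient 0.9: ESS ~ n (1 - 0.9)/(1 + 0.9)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n, sd = sqrt(1 - 0.81)))
  rep_ar <- convergence_report(fake_draws(matrix(exp(x), ncol = 1)))
  expect_equal(rep_ar$ess, n * 0.1 / 1.9, tolerance = 0.3)
})

test_that("constant chains are flagged, short chains rejected", {
  const <- fake_draws(matrix(1, 500, 1))
  rep_c <- convergence_report(const)
  expect_true(rep_c$flagged)
  expect_true(is.na(rep_c$ess))
  expect_error(convergence_report(fake_draws(matrix(exp(rnorm(100)),
                                                    ncol = 1))), "200")
})
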