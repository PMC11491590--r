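test_that("incidence log-likelihood matches Poisson pmf evaluations", {
  d1 <- incidence_data("A", 0L, 1)
  expect_equal(incidence_loglik(d1, 0, 0), -1)
  d2 <- incidence_data("A", 2L, 1)
  expect_equal(incidence_loglik(d2, 0, 0), -1 - log(2))
  # additivity over areas
  d3 <- incidence_data(c("A", "B"), c(2L, 2L), c(1, 1))
  expect_equal(incidence_loglik(d3, 0, c(0, 0)),
               2 * incidence_loglik(d2, 0, 0))
  expect_error(incidence_loglik(d3, 0, 0), "length")
})

test_that("incidence likelihood is maximized at mu = log(sum(y)/sum(E))", {
  set.seed(5)
  d <- incidence_data(paste0("a", 1:6), rpois(6, 20), runif(6, 5, 30))
  mu_hat <- log(sum(d$observed) / sum(d$expected))
  opt <- optimize(function(m) incidence_loglik(d, m, rep(0, 6)),
                  c(-3, 3), maximum = TRUE)
  expect_equal(opt$maximum, mu_hat, tolerance = 1e-4)
})

test_that("excess-hazard log-likelihood matches direct evaluation", {
  s1 <- survival_data("A", 1L, 0L, 0.5, 1)
  expect_equal(excess_hazard_loglik(s1, 0.5, 0), -1)  # mean = 1, d = 0
  s2 <- survival_data("A", 1L, 1L, 0, 2)
  expect_equal(excess_hazard_loglik(s2, 0.5, 0), -1)  # mean = 1, d = 1
  # S -> -Inf: excess term vanishes, background-only Poisson remains
  s3 <- survival_data("A", 1L, 3L, 2.5, 10)
  expect_equal(excess_hazard_loglik(s3, 0.4, -50), dpois(3, 2.5, log = TRUE))
  # zero-mean cell with observed deaths: flagged -Inf, not an error
  s4 <- survival_data("A", 1L, 2L, 0, 1)
  ll <- excess_hazard_loglik(s4, 1e-300, -700)
  expect_identical(as.numeric(ll), -Inf)
  expect_false(is.null(attr(ll, "flagged")))
})

test_that("data validators reject malformed inputs", {
  expect_error(incidence_data("A", -1L, 1), "non-negative")
  expect_error(incidence_data("A", 1.5, 1), "integer")
  expect_error(incidence_data("A", 1L, 0), "positive")
  expect_error(survival_data(c("A", "A"), c(1L, 1L), c(0L, 0L), c(1, 1),
                             c(1, 1)), "duplicate")
  expect_error(survival_data(c("A", "B"), c(1L, 2L), c(0L, 0L), c(1, 1),
                             c(1, 1)), "complete")
})

test_that("log-posterior decomposes and matches a dense MVN oracle", {
  g <- build_graph(cbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  d <- incidence_data(c("A", "B", "C"), c(4L, 6L, 2L), c(5, 5, 5))
  pr <- car_priors()

  # S = 0, rho = 0: CAR term reduces to iid normals at zero
  p0 <- list(mu = 0.1, S = rep(0, 3), rho = 0, sigma2 = 0.3)
  hyper <- log(2) + dnorm(sqrt(0.3), 0, 1, log = TRUE) +
    dnorm(0.1, 0, 10, log = TRUE)
  expect_equal(log_posterior(p0, d, g, pr),
               incidence_loglik(d, 0.1, rep(0, 3)) -
                 1.5 * log(2 * pi * 0.3) + hyper)

  # general params: dense linear-algebra oracle for the CAR prior density
  p1 <- list(mu = -0.2, S = c(0.3, -0.1, 0.4), rho = 0.6, sigma2 = 0.5)
  Qd <- as.matrix(leroux_precision(g, 0.6, 0.5))
  mvn <- 0.5 * log(det(Qd)) - 0.5 * drop(p1$S %*% Qd %*% p1$S) -
    1.5 * log(2 * pi)
  hyper1 <- log(2) + dnorm(sqrt(0.5), 0, 1, log = TRUE) +
    dnorm(-0.2, 0, 10, log = TRUE)
  expect_equal(log_posterior(p1, d, g, pr),
               incidence_loglik(d, -0.2, p1$S) + mvn + hyper1)
  expect_error(log_posterior(list(mu = 0, S = 0, rho = 0, sigma2 = 1),
                             d, g, pr), "length")
})

test_that("log-posterior is continuous near interior points", {
  g <- make_lattice(2, 2)
  d <- incidence_data(g$area_ids, c(3L, 5L, 4L, 6L), rep(4, 4))
  base <- list(mu = 0.1, S = c(0.1, -0.2, 0, 0.15), rho = 0.5, sigma2 = 0.2)
  f0 <- log_posterior(base, d, g)
  for (eps in c(1e-4, 1e-6)) {
    pert <- base
    pert$mu <- base$mu + eps
    pert$rho <- base$rho + eps
    pert$sigma2 <- base$sigma2 + eps
    expect_lt(abs(log_posterior(pert, d, g) - f0), 1e-2)
  }
})
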