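test_that("log-likelihood equals the Gaussian density closed form at the mean", {
  # all pairs sit exactly at their null mean with sigma_ij = 1:
  # each pair contributes -log(1) - 1/2 log(2 pi) - 0 per window
  n <- 3
  a <- c(0.4, 0.5, 0.6)
  mu <- outer(a, a)
  arr <- array(0, c(n, n, 1))
  arr[, , 1] <- mu
  diag(arr[, , 1]) <- 0
  dfc <- dfc_tensor(arr)
  params <- latent_params(a, rep(1, n))
  expect_equal(loglikelihood(dfc, params), 3 * (-0.5 * log(2 * pi)), tolerance = 1e-12)
})

test_that("doubling all residuals quadruples the quadratic likelihood term", {
  n <- 4
  a <- rep(0.5, n)
  b <- rep(0.6, n)
  mu <- outer(a, a)
  shift <- function(d) {
    arr <- array(0, c(n, n, 2))
    for (t in 1:2) {
      sl <- mu + d
      diag(sl) <- 0
      arr[, , t] <- sl
    }
    dfc_tensor(arr)
  }
  p <- latent_params(a, b)
  ll0 <- loglikelihood(shift(0), p)
  ll1 <- loglikelihood(shift(0.01), p)
  ll2 <- loglikelihood(shift(0.02), p)
  expect_equal(ll0 - ll2, 4 * (ll0 - ll1), tolerance = 1e-9)
})

test_that("log-likelihood matches a naive term-by-term summation oracle", {
  dfc <- random_tensor(5, 10, seed = 21)
  withr::with_seed(22, {
    p <- latent_params(runif(5, 0.2, 0.9), runif(5, 0.2, 0.9))
  })
  tau <- 10
  acc <- 0
  for (i in 1:4) {
    for (j in (i + 1):5) {
      sig <- p$b[i] * p$b[j]
      mu <- p$a[i] * p$a[j]
      acc <- acc - tau * log(sig) - tau / 2 * log(2 * pi)
      for (t in seq_len(tau)) {
        acc <- acc - (dfc$weights[i, j, t] - mu)^2 / (2 * sig^2)
      }
    }
  }
  expect_equal(loglikelihood(dfc, p), acc, tolerance = 1e-10)
})

test_that("degree initialization reproduces the closed-form examples", {
  # identical time-mean weights for all pairs -> a_i = 1/N
  dfc <- homogeneous_tensor(n = 6, m = 0.4, s = 0.02)
  init <- init_params(dfc)
  expect_equal(init$a, rep(1 / 6, 6), tolerance = 1e-12)

  # N = 3 with wbar = {0.4, 0.4, 0.2} -> a_1 = 0.8 / 2.0
  arr <- array(0, c(3, 3, 2))
  wbar <- matrix(0, 3, 3)
  wbar[1, 2] <- wbar[2, 1] <- 0.4
  wbar[1, 3] <- wbar[3, 1] <- 0.4
  wbar[2, 3] <- wbar[3, 2] <- 0.2
  for (t in 1:2) arr[, , t] <- wbar
  init2 <- init_params(dfc_tensor(arr))
  expect_equal(init2$a[1], 0.4, tolerance = 1e-12)

  # the a-vector sums to one when no clipping triggers
  dfc3 <- random_tensor(8, 5, seed = 4)
  expect_equal(sum(init_params(dfc3)$a), 1, tolerance = 1e-12)
})

test_that("estimating equations match a naive double-loop oracle", {
  dfc <- random_tensor(6, 7, seed = 31)
  withr::with_seed(32, {
    p <- latent_params(runif(6, 0.2, 0.9), runif(6, 0.2, 0.9))
  })
  res <- estimating_equations(dfc, p)
  n <- 6
  tau <- 7
  wbar <- apply(dfc$weights, c(1, 2), mean)
  expected <- numeric(2 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      expected[i] <- expected[i] + p$a[i] * p$a[j] - wbar[i, j]
      v_ij <- 0
      for (t in seq_len(tau)) {
        v_ij <- v_ij + (dfc$weights[i, j, t] - p$a[i] * p$a[j])^2 / tau
      }
      expected[n + i] <- expected[n + i] - (p$b[i] * p$b[j])^2 + v_ij
    }
  }
  expect_equal(res, expected, tolerance = 1e-12)
})

test_that("residuals vanish in the homogeneous closed form", {
  m <- 0.36
  dfc <- homogeneous_tensor(n = 5, m = m, s = 0)
  p <- suppressWarnings(latent_params(rep(sqrt(m), 5), rep(1e-9, 5)))
  res <- estimating_equations(dfc, p)
  expect_true(max(abs(res)) < 1e-12)
})

test_that("residuals at the true parameters shrink with tau", {
  taus <- c(50, 200, 800)
  norms <- sapply(taus, function(tau) {
    mean(sapply(1:20, function(s) {
      sim <- simulate_null_tensor(synthetic_spec(10, tau, seed = 1000 + s))
      p <- latent_params(sim$truth$a_true, sim$truth$b_true)
      max(abs(estimating_equations(sim$dfc, p)))
    }))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("the solver recovers the homogeneous closed form to 1e-8", {
  m <- 0.25
  s <- 0.04
  fit <- solve_latent(homogeneous_tensor(n = 5, m = m, s = s))
  expect_true(fit$converged)
  expect_true(max(abs(fit$a - sqrt(m))) < 1e-8)
  expect_true(max(abs(fit$b - sqrt(s))) < 1e-8)
})

test_that("converged solutions drive the printed equations below tolerance", {
  for (seed in c(11, 12, 13)) {
    dfc <- random_tensor(8, 30, seed = seed)
    fit <- solve_latent(dfc)
    expect_true(fit$converged)
    expect_lte(max(abs(estimating_equations(dfc, fit))), 1e-10)
  }
})

test_that("latent parameters are recovered from null-simulated data", {
  sim <- simulate_null_tensor(synthetic_spec(30, 500, seed = 71))
  fit <- solve_latent(sim$dfc)
  expect_true(fit$converged)
  expect_lt(sqrt(mean((fit$a - sim$truth$a_true)^2)), 0.05)
  expect_lt(sqrt(mean((fit$b - sim$truth$b_true)^2)), 0.1)
})

test_that("moment solution agrees with direct likelihood maximization when homogeneous", {
  dfc <- homogeneous_tensor(n = 5, m = 0.25, s = 0.04, tau = 4)
  fit_mom <- solve_latent(dfc)
  fit_dir <- fit_latent_direct(dfc)
  expect_true(max(abs(fit_mom$a - fit_dir$a)) < 1e-6)
  expect_true(max(abs(fit_mom$b - fit_dir$b)) < 1e-6)
})

test_that("rescaling all weights by k^2 scales the recovered a by k", {
  k <- 0.5
  dfc <- homogeneous_tensor(n = 5, m = 0.8, s = 0.1)
  scaled <- dfc_tensor(dfc$weights * k^2)
  f1 <- solve_latent(dfc)
  f2 <- solve_latent(scaled)
  expect_equal(f2$a, k * f1$a, tolerance = 1e-8)

  # heterogeneous case, to solver tolerance
  het <- random_tensor(6, 20, seed = 9)
  g1 <- solve_latent(het)
  g2 <- solve_latent(dfc_tensor(het$weights * k^2))
  expect_equal(g2$a, k * g1$a, tolerance = 1e-6)
})

test_that("fitting improves the likelihood over the initialization", {
  wins <- sapply(1:10, function(s) {
    sim <- simulate_null_tensor(synthetic_spec(12, 60, seed = 400 + s))
    init <- init_params(sim$dfc)
    fit <- solve_latent(sim$dfc)
    loglikelihood(sim$dfc, fit) >= loglikelihood(sim$dfc, init)
  })
  expect_gte(sum(wins), 9)
})

test_that("pair distributions are outer products with a floored sigma", {
  p <- latent_params(c(0.5, 0.5, 0.5), c(0.2, 0.3, 0.4))
  d <- pair_distributions(p)
  expect_true(all(d$mu[upper.tri(d$mu)] == 0.25))
  expect_identical(d$mu, t(d$mu))
  expect_equal(d$sigma[1, 2], 0.06)

  tiny <- suppressWarnings(latent_params(c(0.5, 0.5, 0.5), rep(1e-9, 3)))
  d2 <- pair_distributions(tiny)
  expect_true(all(d2$sigma >= 1e-12))
  expect_equal(d2$sigma[1, 2], 1e-12)

  withr::with_seed(3, {
    pr <- latent_params(runif(6, 0.1, 1), runif(6, 0.1, 1))
  })
  d3 <- pair_distributions(pr)
  expect_identical(d3$mu, t(d3$mu))
  expect_identical(d3$sigma, t(d3$sigma))
})

test_that("domain errors are raised for invalid parameters", {
  expect_error(latent_params(c(0.5, -0.1, 0.3), rep(0.2, 3)), "strictly positive")
  expect_warning(latent_params(c(0.5, 1.2, 0.3), rep(0.2, 3)), "exceed 1")
  dfc <- homogeneous_tensor()
  expect_error(init_params(dfc_tensor(array(0, c(3, 3, 2)))), "total summed weight")
})
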