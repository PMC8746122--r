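test_that("percentile thresholds sit at the fitted Gaussian quantile", {
  p <- latent_params(rep(sqrt(0.5), 3), rep(sqrt(0.1), 3))
  d <- pair_distributions(p) # mu = 0.5, sigma = 0.1 for every pair
  thr <- percentile_threshold(d, alpha = 0.2)
  z80 <- z_quantile_bisect(0.8) # independent quantile routine
  expect_equal(thr[1, 2], 0.5 + 0.1 * z80, tolerance = 1e-9)

  # alpha = 0.5: the threshold is the median, i.e. mu itself
  expect_equal(percentile_threshold(d, 0.5)[1, 2], 0.5, tolerance = 1e-12)

  # degenerate spread: threshold collapses onto mu
  tiny <- suppressWarnings(latent_params(rep(sqrt(0.5), 3), rep(1e-9, 3)))
  expect_equal(percentile_threshold(pair_distributions(tiny), 0.01)[1, 2], 0.5,
               tolerance = 1e-9)
})

test_that("link p values invert the percentile threshold", {
  expect_equal(link_pvalue(0.5, 0.5, 0.1), 0.5)
  z80 <- qnorm(0.8)
  expect_equal(link_pvalue(0.5 + 0.1 * z80, 0.5, 0.1), 0.2, tolerance = 1e-12)
  grid <- seq(0, 1, by = 0.05)
  pv <- link_pvalue(grid, 0.5, 0.1)
  expect_true(all(diff(pv) < 0))
  expect_error(link_pvalue(0.5, 0.5, 0), "strictly positive")
})

test_that("flags, counts and the exceedance extremes behave as constructed", {
  n <- 4
  tau <- 6
  p <- latent_params(rep(0.5, n), rep(0.5, n))
  d <- pair_distributions(p) # mu = 0.25, sigma = 0.25
  low <- array(0.01, c(n, n, tau))
  for (t in seq_len(tau)) diag(low[, , t]) <- 0
  fl <- flag_windows(dfc_tensor(low), d)
  expect_true(all(fl$counts == 0))

  hot <- array(0.25 + 10 * 0.25, c(n, n, tau))
  for (t in seq_len(tau)) diag(hot[, , t]) <- 0
  fl2 <- flag_windows(dfc_tensor(hot), d)
  expect_true(all(fl2$counts[upper.tri(diag(n))] == tau))
})

test_that("the per-window flag rate is calibrated under the exact null", {
  sim <- simulate_null_tensor(synthetic_spec(30, 200, seed = 91))
  truth_params <- latent_params(sim$truth$a_true, sim$truth$b_true)
  fl <- flag_windows(sim$dfc, pair_distributions(truth_params),
                     significance_config(alpha = 0.2))
  n_flags <- 30 * 29 / 2 * 200
  rate <- sum(fl$counts[upper.tri(fl$counts)]) / n_flags
  se <- sqrt(0.2 * 0.8 / n_flags)
  expect_lt(abs(rate - 0.2), 3 * se)
})

test_that("admission requires strictly more than half the windows", {
  counts <- matrix(0L, 3, 3)
  counts[1, 2] <- counts[2, 1] <- 11L
  counts[1, 3] <- counts[3, 1] <- 10L
  b <- aggregate_backbone(counts, tau = 20)
  expect_identical(b[1, 2], 1L)
  expect_identical(b[1, 3], 0L) # exactly tau/2 is rejected
  expect_true(all(aggregate_backbone(matrix(0L, 3, 3), 20) == 0))
})

test_that("flag decisions and p values are exactly coherent", {
  sim <- simulate_null_tensor(synthetic_spec(12, 25, seed = 55))
  fit <- solve_latent(sim$dfc)
  for (alpha in c(0.05, 0.2, 0.4)) {
    cfg <- significance_config(alpha = alpha)
    fl <- flag_windows(sim$dfc, pair_distributions(fit), cfg)
    mask <- array(rep(upper.tri(diag(12)) | lower.tri(diag(12)), 25), dim = dim(fl$flags))
    expect_identical(fl$flags[mask] == 1L, fl$pvals[mask] < alpha)
  }
})

test_that("raising alpha never decreases exceedance counts", {
  dfc <- random_tensor(10, 20, seed = 77)
  fit <- solve_latent(dfc)
  d <- pair_distributions(fit)
  counts <- lapply(c(0.05, 0.1, 0.2, 0.5), function(a) {
    flag_windows(dfc, d, significance_config(alpha = a))$counts
  })
  for (k in 1:3) {
    expect_true(all(counts[[k + 1]] >= counts[[k]]))
  }
})

test_that("a low-weight tie with a low fitted mean can beat a heavier tie", {
  # pair (1,2): weights 0.2 but mu* = 0.05, sigma* = 0.01 -> far above threshold
  # pair (3,4): weights 0.6 but mu* = 0.7  -> below its own threshold
  a <- c(0.2, 0.25, 0.8, 0.875)
  b <- c(0.1, 0.1, 0.1, 0.1)
  p <- latent_params(a, b)
  d <- pair_distributions(p)
  expect_equal(d$mu[1, 2], 0.05)
  expect_equal(d$mu[3, 4], 0.7)
  arr <- array(0.4, c(4, 4, 10))
  for (t in 1:10) {
    arr[1, 2, t] <- arr[2, 1, t] <- 0.2
    arr[3, 4, t] <- arr[4, 3, t] <- 0.6
    diag(arr[, , t]) <- 0
  }
  cfg <- significance_config(alpha = 0.1)
  fl <- flag_windows(dfc_tensor(arr), d, cfg)
  bin <- aggregate_backbone(fl$counts, 10, cfg)
  expect_identical(bin[1, 2], 1L)
  expect_identical(bin[3, 4], 0L)
})

test_that("the weighted backbone averages threshold exceedances on admitted links", {
  n <- 4
  tau <- 8
  thr <- matrix(0.5, n, n)
  binary <- matrix(0L, n, n)
  binary[1, 2] <- binary[2, 1] <- 1L
  binary[1, 3] <- binary[3, 1] <- 1L
  arr <- array(0.5, c(n, n, tau))
  d <- 0.07
  for (t in seq_len(tau)) {
    arr[1, 2, t] <- arr[2, 1, t] <- 0.5 + d
    # antisymmetric fluctuation around the threshold
    arr[1, 3, t] <- arr[3, 1, t] <- 0.5 + ifelse(t %% 2 == 0, 0.1, -0.1)
    arr[2, 3, t] <- arr[3, 2, t] <- 0.9 # heavy but not admitted
    diag(arr[, , t]) <- 0
  }
  wb <- weighted_backbone(dfc_tensor(arr), thr, binary)
  expect_equal(wb[1, 2], d, tolerance = 1e-12)
  expect_equal(wb[1, 3], 0, tolerance = 1e-12)
  expect_equal(wb[2, 3], 0) # masked despite exceeding
  wb_pos <- weighted_backbone(dfc_tensor(arr), thr, binary, measure = "positive_mean")
  expect_equal(wb_pos[1, 3], 0.05, tolerance = 1e-12)
})

test_that("share of significant ties divides backbone degree by N - 1", {
  full <- matrix(1L, 5, 5) - diag(1L, 5)
  expect_true(all(share_significant_ties(full)$share == 1))
  expect_true(all(share_significant_ties(matrix(0L, 5, 5))$share == 0))
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1L
  sh <- share_significant_ties(star)$share
  expect_equal(sh, c(1, 0.25, 0.25, 0.25, 0.25))
})

test_that("group consensus averages subjects and floors only the display copy", {
  b <- matrix(0L, 4, 4)
  b[1, 2] <- b[2, 1] <- 1L
  cons <- group_consensus(list(b, b, b))
  expect_equal(cons$mean, b * 1.0, ignore_attr = TRUE)

  # a tie admitted in 1 of 150 subjects survives in mean but not display
  many <- c(list(b), replicate(149, matrix(0L, 4, 4), simplify = FALSE))
  cons2 <- group_consensus(many)
  expect_equal(cons2$mean[1, 2], 1 / 150, tolerance = 1e-12)
  expect_identical(cons2$display[1, 2], 0)
  expect_true(all(cons2$mean >= 0 & cons2$mean <= 1))
  expect_error(group_consensus(list()), "at least one")
})

test_that("Bonferroni-style corrections tighten the effective alpha", {
  dfc <- random_tensor(6, 10, seed = 13)
  fit <- solve_latent(dfc)
  bb_none <- extract_backbone(dfc, fit, significance_config(alpha = 0.2))
  bb_cnt <- extract_backbone(dfc, fit,
                             significance_config(alpha = 0.2, correction = "bonferroni_count"))
  expect_equal(bb_cnt$alpha_effective, 0.2 / choose(6, 2))
  expect_true(all(bb_cnt$counts <= bb_none$counts))
  expect_warning(significance_config(correction = "bonferroni_weight_sum"),
                 "total summed edge weight")
})

test_that("backbone results tidy into per-pair tibbles", {
  sim <- simulate_null_tensor(synthetic_spec(8, 15, seed = 2))
  bb <- extract_backbone(sim$dfc)
  td <- tidy(bb)
  expect_equal(nrow(td), choose(8, 2))
  expect_true(all(td$count >= 0 & td$count <= 15))
  g <- glance(bb)
  expect_identical(g$n_admitted, sum(bb$binary[upper.tri(bb$binary)]))
  expect_symmetric_zero_diag(bb$binary)
  expect_symmetric_zero_diag(bb$counts)
})
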