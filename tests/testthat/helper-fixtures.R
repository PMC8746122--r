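# fixtures built in code; no data files

# homogeneous tensor: every pair has weights m + s * z_t with z = (+1, -1)
# repeated, so the time-mean is exactly m and the per-pair population SD
# exactly s; the latent solution is a_i = sqrt(m), b_i = sqrt(s) in closed form
homogeneous_tensor <- function(n = 5, m = 0.25, s = 0.04, tau = 2) {
  stopifnot(tau %% 2 == 0)
  z <- rep(c(1, -1), length.out = tau)
  arr <- array(0, c(n, n, tau))
  for (t in seq_len(tau)) {
    sl <- matrix(m + s * z[t], n, n)
    diag(sl) <- 0
    arr[, , t] <- sl
  }
  dfc_tensor(arr)
}

# small random tensor with positive weights (uniform), for oracle comparisons
random_tensor <- function(n, tau, seed, lo = 0.05, hi = 0.95) {
  withr::with_seed(seed, {
    arr <- array(0, c(n, n, tau))
    for (t in seq_len(tau)) {
      v <- runif(n * (n - 1) / 2, lo, hi)
      sl <- matrix(0, n, n)
      sl[upper.tri(sl)] <- v
      arr[, , t] <- sl + t(sl)
    }
    dfc_tensor(arr)
  })
}

# brute-force Pearson correlation via explicit two-pass mean/SD/covariance
cor_two_pass <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sx <- sqrt(sum((x - mx)^2))
  sy <- sqrt(sum((y - my)^2))
  sxy / (sx * sy)
}

# standard normal quantile by bisection of pnorm (independent of qnorm)
z_quantile_bisect <- function(p, tol = 1e-12) {
  lo <- -10
  hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

expect_symmetric_zero_diag <- function(m, tol = 0) {
  expect_true(all(abs(m - t(m)) <= tol))
  expect_true(all(diag(m) == 0))
}
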