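test_that("window boundaries follow the stride rule", {
  w <- make_windows(100, width = 20, overlap = 5)
  expect_identical(w$starts, as.integer(c(0, 15, 30, 45, 60, 75)))
  expect_identical(w$n_windows, 6L)

  w2 <- make_windows(10, width = 5, overlap = 0)
  expect_identical(w2$starts, c(0L, 5L))

  expect_error(make_windows(20, width = 20, overlap = 5), "fewer than 2 windows")
  expect_error(make_windows(100, width = 20, overlap = 20), "overlap")
  expect_error(make_windows(10, width = 20, overlap = 0), "width")
})

test_that("windows stay inside the series and overlap by exactly o", {
  cases <- list(c(97, 13, 4), c(200, 20, 5), c(50, 7, 0), c(64, 16, 15))
  for (cs in cases) {
    w <- make_windows(cs[1], cs[2], cs[3])
    ends <- w$starts + w$width
    expect_true(all(w$starts >= 0) && all(ends <= cs[1]))
    if (w$n_windows > 1) {
      shared <- ends[-w$n_windows] - w$starts[-1]
      expect_true(all(shared == cs[3]))
    }
    td <- tidy(w)
    expect_identical(nrow(td), w$n_windows)
  }
})

test_that("windowed correlation handles perfect, anti- and null correlation", {
  set.seed(1)
  base <- rnorm(10)
  x <- cbind(a = base, b = base, c = -base, d = rnorm(10))
  w <- make_windows(10, 5, 0)
  arr <- windowed_correlation(x, w)
  expect_equal(arr["a", "b", 1], 1)
  expect_equal(arr["a", "c", 1], -1)

  set.seed(42)
  noise <- matrix(rnorm(10000 * 3), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  w2 <- make_windows(10000, 5000, 0)
  arr2 <- windowed_correlation(noise, w2)
  expect_true(all(abs(arr2[upper.tri(diag(3))]) < 0.05))
})

test_that("a constant node raises a named degenerate-signal error", {
  x <- cbind(a = rnorm(20), b = c(rep(1, 10), rnorm(10)), c = rnorm(20))
  w <- make_windows(20, 10, 0)
  expect_error(windowed_correlation(x, w), "node 'b' is constant within window 1")
})

test_that("windowed correlation matches a two-pass oracle to 1e-12", {
  set.seed(7)
  x <- matrix(rnorm(60 * 5), ncol = 5, dimnames = list(NULL, letters[1:5]))
  w <- make_windows(60, 20, 10)
  arr <- windowed_correlation(x, w)
  for (t in seq_len(w$n_windows)) {
    idx <- (w$starts[t] + 1):(w$starts[t] + w$width)
    for (i in 1:4) {
      for (j in (i + 1):5) {
        expect_equal(arr[i, j, t], cor_two_pass(x[idx, i], x[idx, j]), tolerance = 1e-12)
        expect_identical(arr[i, j, t], arr[j, i, t])
      }
    }
    expect_true(all(diag(arr[, , t]) == 0))
  }
})

test_that("min-max rescaling maps the global range onto [0, 1] affinely", {
  arr <- array(0, c(3, 3, 2))
  arr[1, 2, 1] <- arr[2, 1, 1] <- -1
  arr[1, 3, 1] <- arr[3, 1, 1] <- 0
  arr[2, 3, 1] <- arr[3, 2, 1] <- 1
  arr[, , 2] <- arr[, , 1]
  dfc <- rescale_minmax(arr)
  expect_equal(dfc$weights[1, 2, 1], 0)
  expect_equal(dfc$weights[1, 3, 1], 0.5)
  expect_equal(dfc$weights[2, 3, 1], 1)
  expect_equal(dfc$rescale_bounds, c(-1, 1))

  # already spanning [0, 1]: identity
  d2 <- rescale_minmax(dfc$weights)
  expect_equal(d2$weights, dfc$weights)

  arr3 <- arr
  arr3[arr3 == -1] <- 0.2
  arr3[arr3 == 0] <- 0.4
  arr3[arr3 == 1] <- 0.6
  d3 <- rescale_minmax(arr3)
  expect_equal(sort(unique(d3$weights[upper.tri(diag(3))])), c(0, 0.5, 1))

  const <- array(0.5, c(3, 3, 2))
  for (t in 1:2) diag(const[, , t]) <- 0
  expect_error(rescale_minmax(const), "degenerate scale")
})

test_that("min-max rescaling preserves the rank order of off-diagonal weights", {
  dfc_raw <- random_tensor(6, 8, seed = 3)
  mask <- array(rep(upper.tri(diag(6)), 8), dim = c(6, 6, 8))
  before <- dfc_raw$weights[mask]
  after <- rescale_minmax(dfc_raw$weights)$weights[mask]
  expect_identical(rank(before), rank(after))
})

test_that("ROI aggregation averages member columns", {
  x <- cbind(a = c(0, 2, 4), b = c(2, 4, 6), c = c(5, 5, 5), d = 1:3)
  out <- aggregate_rois(x, c("r1", "r1", "r2", "r3"))
  expect_named(out, c("r1", "r2", "r3"))
  expect_equal(out$r1, c(1, 3, 5))
  expect_equal(out$r2, c(5, 5, 5))

  # identical columns collapse to themselves
  y <- cbind(a = 1:5 + 0.5, b = 1:5 + 0.5, c = rnorm(5), d = rnorm(5))
  expect_equal(aggregate_rois(y, c("r", "r", "s", "t"))$r, y[, "a"])

  # singleton regions: column permutation of the input
  out2 <- aggregate_rois(x, c("p", "q", "r", "s"))
  expect_equal(as.matrix(out2), x, ignore_attr = TRUE)

  expect_error(aggregate_rois(x, c("r1", "r2")), "one entry per node")
})

test_that("binarization cuts strictly above the network-wide mean", {
  const <- homogeneous_tensor(n = 4, m = 0.3, s = 0)
  expect_true(all(binarize_tensor(const) == 0))

  # single hot entry in an otherwise-zero tensor
  arr <- array(0, c(4, 4, 3))
  arr[1, 2, 2] <- arr[2, 1, 2] <- 1
  b <- binarize_tensor(dfc_tensor(arr))
  expect_identical(sum(b), 2L)
  expect_identical(b[1, 2, 2], 1L)
  expect_identical(b[2, 1, 2], 1L)

  # half zeros, half ones: mean 0.5, the ones survive the strict cut
  arr2 <- array(0, c(3, 3, 2))
  arr2[1, 2, 1] <- arr2[2, 1, 1] <- 1
  arr2[1, 3, 1] <- arr2[3, 1, 1] <- 0
  arr2[2, 3, 1] <- arr2[3, 2, 1] <- 1
  arr2[1, 2, 2] <- arr2[2, 1, 2] <- 0
  arr2[1, 3, 2] <- arr2[3, 1, 2] <- 1
  arr2[2, 3, 2] <- arr2[3, 2, 2] <- 0
  mean_off <- mean(arr2[array(c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE), c(3, 3, 2))])
  expect_equal(mean_off, 0.5)
  b2 <- binarize_tensor(dfc_tensor(arr2))
  expect_identical(b2[1, 2, 1], 1L)
  expect_identical(b2[1, 3, 1], 0L)
  expect_identical(b2[1, 3, 2], 1L)
})

test_that("every produced slice is symmetric with a zero diagonal", {
  set.seed(5)
  x <- matrix(rnorm(80 * 5), ncol = 5)
  dfc <- build_dfc(x, width = 20, overlap = 5)
  for (t in seq_len(dim(dfc$weights)[3])) {
    expect_symmetric_zero_diag(dfc$weights[, , t])
  }
  bin <- binarize_tensor(dfc)
  for (t in seq_len(dim(bin)[3])) expect_symmetric_zero_diag(bin[, , t])
})
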