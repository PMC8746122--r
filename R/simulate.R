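#' Specification of a synthetic null-model dataset
#'
#' Collects everything the synthetic generators need so that a dataset is a
#' pure function of its spec (bit-reproducible given the same seed). The
#' default parameter ranges match the parameter-recovery study conditions:
#' latent propensities drawn uniformly from `(0.2, 0.9)`.
#'
#' @param n_nodes Number of nodes N (>= 3).
#' @param tau Number of temporal windows.
#' @param a_range,b_range Intervals within `(0, 1]` the latent `a_i` / `b_i`
#'   are drawn from (uniformly).
#' @param planted_pairs Optional integer matrix or data frame with columns
#'   `i, j` (off-diagonal, no duplicates) marking pairs that
#'   [plant_significant_ties()] will elevate.
#' @param seed Integer seed.
#' @param clip Clip generated weights into `[0, 1]`? Default FALSE: the
#'   Gaussian null has unbounded support and clipping would bias recovery
#'   tests; enable it for realism experiments only.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_nodes, tau, a_range = c(0.2, 0.9),
                           b_range = c(0.2, 0.9), planted_pairs = NULL,
                           seed = 1L, clip = FALSE) {
  n_nodes <- as.integer(n_nodes)
  tau <- as.integer(tau)
  if (n_nodes < 3L) abort("`n_nodes` must be at least 3")
  if (tau < 1L) abort("`tau` must be at least 1")
  check_range <- function(r, nm) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] <= 0 || r[2L] > 1) {
      abort(sprintf("`%s` must be an interval within (0, 1]", nm))
    }
  }
  check_range(a_range, "a_range")
  check_range(b_range, "b_range")
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.matrix(planted_pairs)[, 1:2, drop = FALSE]
    storage.mode(planted_pairs) <- "integer"
    if (any(planted_pairs < 1L | planted_pairs > n_nodes)) abort("planted pair indices out of range")
    if (any(planted_pairs[, 1L] == planted_pairs[, 2L])) abort("planted pairs must be off-diagonal")
    key <- paste(pmin(planted_pairs[, 1L], planted_pairs[, 2L]),
                 pmax(planted_pairs[, 1L], planted_pairs[, 2L]))
    if (anyDuplicated(key)) abort("planted pairs must be unique (unordered)")
  }
  structure(
    list(n_nodes = n_nodes, tau = tau, a_range = a_range, b_range = b_range,
         planted_pairs = planted_pairs, seed = as.integer(seed), clip = clip),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> N=%d, tau=%d, a~U(%g,%g), b~U(%g,%g), seed=%d%s\n",
    x$n_nodes, x$tau, x$a_range[1L], x$a_range[2L],
    x$b_range[1L], x$b_range[2L], x$seed, if (x$clip) ", clipped" else ""
  ))
  invisible(x)
}

new_ground_truth <- function(a_true, b_true, n, planted_pairs = NULL) {
  planted <- matrix(0L, n, n)
  if (!is.null(planted_pairs)) {
    for (r in seq_len(nrow(planted_pairs))) {
      i <- planted_pairs[r, 1L]
      j <- planted_pairs[r, 2L]
      planted[i, j] <- planted[j, i] <- 1L
    }
  }
  structure(
    list(a_true = a_true, b_true = b_true,
         planted_mask = planted, injected_mask = matrix(0L, n, n)),
    class = "wbn_ground_truth"
  )
}

#' @export
print.wbn_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<wbn_ground_truth> %d nodes | %d planted, %d injected pairs\n",
    length(x$a_true), sum(utri(x$planted_mask)), sum(utri(x$injected_mask))
  ))
  invisible(x)
}

#' Simulate a dynamic-connectivity tensor from the latent null model
#'
#' Draws latent propensities `a_i, b_i` uniformly from the spec's ranges and
#' then, for every unordered pair and window, one weight from
#' `Normal(a_i a_j, (b_i b_j)^2)` (i.i.d. over windows, symmetrized by a
#' single draw per unordered pair). Diagonals are zero.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `dfc` (a [dfc_tensor()]) and `truth`
#'   (latent values and planted/injected masks).
#' @examples
#' sim <- simulate_null_tensor(synthetic_spec(n_nodes = 8, tau = 50, seed = 42))
#' glance(sim$dfc)
#' @export
simulate_null_tensor <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  tau <- spec$tau
  out <- withr::with_seed(spec$seed, {
    a <- stats::runif(n, spec$a_range[1L], spec$a_range[2L])
    b <- stats::runif(n, spec$b_range[1L], spec$b_range[2L])
    mu <- outer(a, a)
    sig <- outer(b, b)
    ut <- upper.tri(diag(n))
    n_pairs <- sum(ut)
    arr <- array(0, dim = c(n, n, tau))
    for (t in seq_len(tau)) {
      w <- stats::rnorm(n_pairs, mean = mu[ut], sd = sig[ut])
      if (spec$clip) w <- pmin(pmax(w, 0), 1)
      arr[, , t] <- sym_from_utri(w, n)
    }
    list(a = a, b = b, arr = arr)
  })
  dfc <- dfc_tensor(out$arr, node_labels = paste0("node_", seq_len(n)))
  truth <- new_ground_truth(out$a, out$b, n, spec$planted_pairs)
  list(dfc = dfc, truth = truth)
}

#' Elevate planted pairs above their null distribution
#'
#' Adds `effect_size * sigma_ij` (with `sigma_ij = b_i b_j` from the ground
#' truth) to every window's weight of each planted pair, providing known
#' positives for calibrating the significance filter.
#'
#' @param dfc A [dfc_tensor()] from [simulate_null_tensor()].
#' @param truth The matching ground truth (its `planted_mask` marks pairs).
#' @param effect_size Shift in units of the pair's null SD (>= 0).
#' @return The modified [dfc_tensor()].
#' @export
plant_significant_ties <- function(dfc, truth, effect_size) {
  stopifnot(inherits(dfc, "dfc_tensor"), inherits(truth, "wbn_ground_truth"))
  if (effect_size < 0) abort("`effect_size` must be nonnegative")
  if (effect_size == 0 || sum(truth$planted_mask) == 0L) return(dfc)
  sig <- outer(truth$b_true, truth$b_true)
  shift <- effect_size * sig * (truth$planted_mask == 1L)
  for (t in seq_len(n_windows_of(dfc))) {
    dfc$weights[, , t] <- dfc$weights[, , t] + shift
  }
  dfc
}

#' Inject random weights into random links
#'
#' Chooses `n_links` off-diagonal pairs uniformly without replacement and
#' overwrites (or adds to) their weights in a fraction of windows with draws
#' from the chosen law, recording the injected pairs in the ground truth.
#' This is the benchmark construction for the injected-link detection
#' experiment.
#'
#' @param dfc A [dfc_tensor()].
#' @param n_links Number of pairs to corrupt.
#' @param seed Integer seed.
#' @param truth Optional ground truth to update (created if omitted, with
#'   `NA` latent values).
#' @param weight_law `"uniform"` (draws from Uniform(0, 1), the default) or
#'   `"constant"` (fixed `value`).
#' @param value Constant weight for `weight_law = "constant"`.
#' @param mode `"overwrite"` (default) or `"add"`.
#' @param window_fraction Fraction of windows (rounded up, chosen at random)
#'   that receive injected weights; default 1 = all windows.
#' @return A list with the modified `dfc` and updated `truth`.
#' @export
inject_random_links <- function(dfc, n_links, seed, truth = NULL,
                                weight_law = c("uniform", "constant"), value = 1,
                                mode = c("overwrite", "add"), window_fraction = 1) {
  stopifnot(inherits(dfc, "dfc_tensor"))
  weight_law <- match.arg(weight_law)
  mode <- match.arg(mode)
  n <- n_nodes(dfc)
  tau <- n_windows_of(dfc)
  n_pairs <- n * (n - 1L) / 2L
  n_links <- as.integer(n_links)
  if (n_links < 0L || n_links > n_pairs) {
    abort(sprintf("`n_links` must be in [0, %d]", n_pairs))
  }
  if (window_fraction <= 0 || window_fraction > 1) abort("`window_fraction` must be in (0, 1]")
  if (is.null(truth)) {
    truth <- new_ground_truth(rep(NA_real_, n), rep(NA_real_, n), n)
  }
  if (n_links == 0L) return(list(dfc = dfc, truth = truth))
  pairs <- upper_pairs(n)
  n_win <- as.integer(ceiling(window_fraction * tau))
  res <- withr::with_seed(seed, {
    chosen <- sample.int(n_pairs, n_links)
    draws <- list()
    wins <- list()
    for (idx in seq_along(chosen)) {
      wins[[idx]] <- if (n_win == tau) seq_len(tau) else sort(sample.int(tau, n_win))
      draws[[idx]] <- switch(weight_law,
        uniform = stats::runif(n_win),
        constant = rep(value, n_win)
      )
    }
    list(chosen = chosen, draws = draws, wins = wins)
  })
  for (idx in seq_along(res$chosen)) {
    i <- pairs$i[res$chosen[idx]]
    j <- pairs$j[res$chosen[idx]]
    truth$injected_mask[i, j] <- truth$injected_mask[j, i] <- 1L
    for (k in seq_along(res$wins[[idx]])) {
      t <- res$wins[[idx]][k]
      v <- res$draws[[idx]][k]
      new_val <- if (mode == "overwrite") v else dfc$weights[i, j, t] + v
      dfc$weights[i, j, t] <- dfc$weights[j, i, t] <- new_val
    }
  }
  list(dfc = dfc, truth = truth)
}

#' Simulate a stationary VAR(1) time series
#'
#' Forward simulation of `x_t = A x_{t-1} + eps_t` from a zero initial state
#' with a discarded burn-in, the generative model that the ARR surrogate
#' scheme assumes.
#'
#' @param n_nodes Number of nodes.
#' @param n_time Series length T (after burn-in).
#' @param A `N x N` coefficient matrix with spectral radius < 1.
#' @param noise_sd Innovation standard deviation (scalar or length-N).
#' @param seed Integer seed.
#' @param burn_in Discarded initial steps (default 200).
#' @return A tibble of node signals (T rows, N columns).
#' @export
simulate_var_series <- function(n_nodes, n_time, A, noise_sd = 1, seed = 1L,
                                burn_in = 200L) {
  n_nodes <- as.integer(n_nodes)
  n_time <- as.integer(n_time)
  check_square(A, n_nodes, "A")
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (sr >= 1) abort(sprintf("unstable VAR: spectral radius %.3f >= 1", sr))
  noise_sd <- rep_len(noise_sd, n_nodes)
  if (any(noise_sd < 0)) abort("`noise_sd` must be nonnegative")
  total <- n_time + as.integer(burn_in)
  x <- withr::with_seed(seed, {
    out <- matrix(0, total, n_nodes)
    state <- numeric(n_nodes)
    for (t in seq_len(total)) {
      state <- as.vector(A %*% state) + stats::rnorm(n_nodes, sd = noise_sd)
      out[t, ] <- state
    }
    out
  })
  x <- x[(as.integer(burn_in) + 1L):total, , drop = FALSE]
  colnames(x) <- paste0("node_", seq_len(n_nodes))
  tibble::as_tibble(x)
}
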