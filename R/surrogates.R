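#' Fit a vector autoregressive model for autoregressive randomization
#'
#' Least-squares estimate of a VAR(p) model `x_t = sum_l A_l x_{t-l} + eps_t`
#' on mean-centered columns, the generative model behind autoregressive
#' randomization (ARR) surrogates.
#'
#' @param ts Time series (data frame or matrix, rows = time points).
#' @param order Autoregressive order `p >= 1`. The fit requires
#'   `T > 10 * order`.
#' @return An `ar_model`: coefficient matrices `A_1 ... A_p` (each `N x N`),
#'   per-node residual standard deviations, the column means removed before
#'   fitting, and bookkeeping fields.
#' @export
fit_ar <- function(ts, order = 1L) {
  x <- as_ts_matrix(ts)
  order <- as.integer(order)
  if (order < 1L) abort("`order` must be at least 1")
  tt <- nrow(x)
  n <- ncol(x)
  if (tt <= 10L * order) {
    abort(sprintf("AR fit needs T > 10 * order (T=%d, order=%d)", tt, order))
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  y <- xc[(order + 1L):tt, , drop = FALSE]
  # intercept absorbs any residual offset the centering leaves behind
  design <- cbind(1, do.call(cbind, lapply(seq_len(order), function(l) {
    xc[(order + 1L - l):(tt - l), , drop = FALSE]
  })))
  fit <- stats::lm.fit(design, y)
  if (fit$rank < ncol(design)) {
    abort(sprintf(
      "singular design matrix in AR fit (rank %d < %d); try a lower order",
      fit$rank, ncol(design)
    ))
  }
  coefs <- fit$coefficients # 1 + (N * p) rows; column i = predictors of node i
  intercept <- coefs[1L, ]
  a_list <- lapply(seq_len(order), function(l) {
    rows <- 1L + (l - 1L) * n + seq_len(n)
    t(coefs[rows, , drop = FALSE]) # A_l[i, k]: effect of x_{t-l}[k] on x_t[i]
  })
  resid <- fit$residuals
  noise_sd <- sqrt(colMeans(resid^2))
  structure(
    list(
      order = order, coefficients = a_list, intercept = intercept,
      noise_sd = noise_sd, means = mu, node_labels = colnames(x), n_time = tt
    ),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf(
    "<ar_model> order %d, %d nodes | spectral radius %.3f | mean noise sd %.3g\n",
    x$order, length(x$noise_sd), ar_spectral_radius(x), mean(x$noise_sd)
  ))
  invisible(x)
}

#' @describeIn fit_ar Long tibble of VAR coefficients (lag, target, source).
#' @param x An `ar_model`.
#' @param ... Unused.
#' @export
#' @method tidy ar_model
tidy.ar_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$order), function(l) {
    a <- x$coefficients[[l]]
    tibble::tibble(
      lag = l,
      target = rep(x$node_labels, times = ncol(a)),
      source = rep(x$node_labels, each = nrow(a)),
      coefficient = as.vector(a)
    )
  })
}

#' Spectral radius of a fitted VAR model's companion matrix
#'
#' Below 1 the model is stationary and ARR surrogates remain bounded.
#'
#' @param model An [fit_ar()] model.
#' @return The largest eigenvalue modulus of the companion matrix.
#' @export
ar_spectral_radius <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  n <- length(model$noise_sd)
  p <- model$order
  comp <- matrix(0, n * p, n * p)
  comp[seq_len(n), ] <- do.call(cbind, model$coefficients)
  if (p > 1L) {
    comp[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

new_surrogate_ensemble <- function(series, method, seed, source_hash, extra = list()) {
  structure(
    c(list(series = series, method = method, seed = seed,
           n_surrogates = length(series), source_hash = source_hash), extra),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  dims <- if (x$n_surrogates > 0L) dim(x$series[[1L]]) else c(NA, NA)
  cat(sprintf(
    "<surrogate_ensemble> method=%s, M=%d, T=%s, N=%s, seed=%d\n",
    x$method, x$n_surrogates, dims[1L], dims[2L], x$seed
  ))
  invisible(x)
}

#' Autoregressive-randomization surrogate time series
#'
#' Each surrogate starts from `p` successive time points drawn uniformly at
#' random from the original series and is extended to length `T` by iterating
#' the fitted VAR recursion with fresh Gaussian innovations (per-node SD from
#' the model residuals). The surrogates preserve the linear lagged dependence
#' structure of the source while destroying everything else.
#'
#' @param model An [fit_ar()] model fitted on `ts`.
#' @param ts The original time series the model was fitted on.
#' @param n_surrogates Number of surrogates M.
#' @param seed Integer seed; the ensemble is a pure function of
#'   `(model, ts, n_surrogates, seed)`.
#' @return A `surrogate_ensemble` with `method = "arr"`.
#' @export
generate_arr <- function(model, ts, n_surrogates, seed) {
  stopifnot(inherits(model, "ar_model"))
  x <- as_ts_matrix(ts)
  tt <- nrow(x)
  n <- ncol(x)
  p <- model$order
  if (length(model$noise_sd) != n) abort("model and series disagree on node count")
  xc <- sweep(x, 2L, model$means)
  series <- withr::with_seed(seed, {
    lapply(seq_len(n_surrogates), function(m) {
      s <- sample.int(tt - p + 1L, 1L)
      out <- matrix(0, tt, n)
      out[seq_len(p), ] <- xc[s:(s + p - 1L), , drop = FALSE]
      for (t in (p + 1L):tt) {
        acc <- model$intercept + stats::rnorm(n, sd = model$noise_sd)
        for (l in seq_len(p)) {
          acc <- acc + as.vector(model$coefficients[[l]] %*% out[t - l, ])
        }
        out[t, ] <- acc
      }
      out <- sweep(out, 2L, model$means, `+`)
      colnames(out) <- colnames(x)
      out
    })
  })
  new_surrogate_ensemble(series, "arr", seed, rlang::hash(x),
                         extra = list(order = p))
}

# Hermitian-symmetric random phase vector: zero at DC (and Nyquist for even T)
random_phase_vector <- function(tt) {
  phi <- numeric(tt)
  if (tt %% 2L == 0L) {
    half <- tt / 2L
    if (half > 1L) {
      draw <- stats::runif(half - 1L, 0, 2 * pi)
      phi[2L:half] <- draw
      phi[(half + 2L):tt] <- -rev(draw)
    }
  } else {
    half <- (tt - 1L) / 2L
    if (half > 0L) {
      draw <- stats::runif(half, 0, 2 * pi)
      phi[2L:(half + 1L)] <- draw
      phi[(half + 2L):tt] <- -rev(draw)
    }
  }
  phi
}

#' Phase-randomization surrogate time series
#'
#' Takes the discrete Fourier transform of every node signal, adds one
#' uniformly distributed random phase per frequency — the same phase vector
#' across all nodes, which preserves cross-spectra and hence zero-lag
#' correlations — enforces Hermitian symmetry so the inverse transform is
#' real, and inverts. Amplitude spectra of the source are preserved exactly,
#' so the surrogates share its full (circular) autocovariance sequence.
#'
#' @param ts Time series (data frame or matrix), `T >= 4`.
#' @param n_surrogates Number of surrogates M.
#' @param seed Integer seed.
#' @param phases Optional list of explicit phase vectors (length `T` each),
#'   overriding the random draw — mainly for verification (an all-zero phase
#'   vector reproduces the source exactly).
#' @return A `surrogate_ensemble` with `method = "pr"`.
#' @export
generate_pr <- function(ts, n_surrogates, seed, phases = NULL) {
  x <- as_ts_matrix(ts)
  tt <- nrow(x)
  if (tt < 4L) abort("phase randomization needs at least 4 time points")
  xf <- stats::mvfft(x)
  make_one <- function(phi) {
    rot <- exp(1i * phi)
    out <- Re(stats::mvfft(xf * rot, inverse = TRUE)) / tt
    colnames(out) <- colnames(x)
    out
  }
  if (!is.null(phases)) {
    if (length(phases) != n_surrogates) abort("`phases` must supply one vector per surrogate")
    series <- lapply(phases, make_one)
  } else {
    series <- withr::with_seed(seed, {
      lapply(seq_len(n_surrogates), function(m) make_one(random_phase_vector(tt)))
    })
  }
  new_surrogate_ensemble(series, "pr", seed, rlang::hash(x))
}

# order statistic used as the empirical (1 - alpha) surrogate quantile:
# the k-th smallest of M values with k = ceiling((1 - alpha) * M)
surrogate_order_stat <- function(m, alpha) {
  k <- as.integer(ceiling((1 - alpha) * m))
  min(max(k, 1L), m)
}

#' Surrogate-based baseline backbone
#'
#' Builds the subject's dynamic-connectivity tensor and M surrogate tensors
#' (same windowing, rescaled with the original subject's min-max bounds so
#' all weights share one scale). A pair-window is flagged when the original
#' weight strictly exceeds the empirical `(1 - alpha)` quantile of that
#' pair-window's M surrogate weights; flags are aggregated with the same
#' `count > count_fraction * tau` rule as the latent-model backbone so the
#' methods are directly comparable.
#'
#' @param ts Original time series (data frame or matrix).
#' @param windows A [make_windows()] segmentation.
#' @param method `"arr"` or `"pr"`.
#' @param n_surrogates Ensemble size `M >= 20`; also needs `M * alpha >= 1`
#'   for the requested quantile to be estimable.
#' @param alpha Upper-tail significance level.
#' @param seed Integer seed for the surrogate draw.
#' @param order VAR order for `method = "arr"`.
#' @param count_fraction Aggregation fraction (default 0.5).
#' @param dfc Optional precomputed [dfc_tensor()] of the original series
#'   (must carry global rescale bounds); built internally when omitted.
#' @return A `backbone_result` whose `pvals` are empirical surrogate
#'   p values `(1 + #{surrogate >= w}) / (M + 1)`.
#' @export
surrogate_backbone <- function(ts, windows, method = c("arr", "pr"),
                               n_surrogates = 50L, alpha = 0.2, seed = 1L,
                               order = 1L, count_fraction = 0.5, dfc = NULL) {
  method <- match.arg(method)
  x <- as_ts_matrix(ts)
  m <- as.integer(n_surrogates)
  if (m < 20L) abort("surrogate testing needs at least 20 surrogates")
  if (m * alpha < 1) {
    abort(sprintf("M * alpha = %.3g < 1: too few surrogates for the %g quantile",
                  m * alpha, 1 - alpha))
  }
  if (is.null(dfc)) {
    dfc <- rescale_minmax(windowed_correlation(x, windows), scope = "global")
  } else {
    stopifnot(inherits(dfc, "dfc_tensor"))
    if (!identical(dfc$scope, "global") || length(dfc$rescale_bounds) != 2L) {
      abort("a supplied `dfc` must carry global rescale bounds")
    }
  }
  bounds <- dfc$rescale_bounds

  ens <- switch(method,
    arr = generate_arr(fit_ar(x, order), x, m, seed),
    pr = generate_pr(x, m, seed)
  )
  n <- ncol(x)
  tau <- windows$n_windows
  # surrogate weights per (pair, window): M x (N * N * tau)
  surr <- array(NA_real_, dim = c(m, n, n, tau))
  for (s in seq_len(m)) {
    sdfc <- rescale_minmax(windowed_correlation(ens$series[[s]], windows),
                           scope = "global", bounds = bounds)
    surr[s, , , ] <- sdfc$weights
  }
  k <- surrogate_order_stat(m, alpha)
  mask <- off_diag(n)
  flags <- array(0L, dim = dim(dfc$weights), dimnames = dimnames(dfc$weights))
  pvals <- array(NA_real_, dim = dim(dfc$weights), dimnames = dimnames(dfc$weights))
  counts <- matrix(0L, n, n, dimnames = dimnames(dfc$weights)[1:2])
  thr_mean <- matrix(0, n, n)
  for (t in seq_len(tau)) {
    w <- dfc$weights[, , t]
    slice <- surr[, , , t] # M x N x N
    thr <- apply(slice, c(2L, 3L), function(v) sort(v)[k])
    w_rep <- aperm(array(w, dim = c(n, n, m)), c(3L, 1L, 2L))
    ge <- apply(slice >= w_rep, c(2L, 3L), sum)
    fl <- matrix(0L, n, n)
    fl[mask] <- as.integer(w[mask] > thr[mask])
    flags[, , t] <- fl
    counts <- counts + fl
    p <- matrix(NA_real_, n, n)
    p[mask] <- (1 + ge[mask]) / (m + 1)
    pvals[, , t] <- p
    thr_mean <- thr_mean + thr
  }
  cfg <- significance_config(alpha = alpha, count_fraction = count_fraction)
  binary <- aggregate_backbone(counts, tau, cfg)
  structure(
    list(
      counts = counts, binary = binary, weighted = NULL, pvals = pvals,
      thresholds = thr_mean / tau, alpha_effective = alpha,
      params = NULL, config = cfg, tau = tau,
      node_labels = dfc$node_labels, method = method,
      n_surrogates = m, seed = seed
    ),
    class = "backbone_result"
  )
}
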