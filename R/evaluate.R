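#' Normality sweep over window sizes
#'
#' For each window size, builds the dynamic-connectivity tensor and tests
#' each pair's `tau` temporal weights against a Gaussian with that pair's
#' sample mean and SD (Kolmogorov-Smirnov), averaging the p values over all
#' `N(N-1)/2` pairs. Because the reference parameters are estimated from the
#' same sample, the plain KS p value is conservative in the Lilliefors sense;
#' `method = "lilliefors"` uses the bias-corrected test (requires the
#' `nortest` package). Zero-variance pairs are skipped and counted.
#'
#' @param ts Time series (data frame or matrix).
#' @param deltas Integer vector of window sizes to sweep.
#' @param overlaps Integer vector of overlaps (recycled against `deltas`).
#' @param method `"ks"` (default) or `"lilliefors"`.
#' @return A `normality_report` tibble: one row per window size with the mean
#'   p value, the window count `tau`, and the number of skipped pairs. The
#'   per-pair p values are attached as a list-column `pvalues`.
#' @export
# per-pair normality p values of a tensor's temporal weight sequences;
# NA marks zero-variance (skipped) pairs
pair_normality_pvalues <- function(dfc, method = "ks") {
  n <- n_nodes(dfc)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pv <- rep(NA_real_, nrow(ut))
  for (r in seq_len(nrow(ut))) {
    w <- dfc$weights[ut[r, 1L], ut[r, 2L], ]
    s <- stats::sd(w)
    if (s == 0) next
    pv[r] <- if (method == "ks") {
      suppressWarnings(stats::ks.test(w, "pnorm", mean = mean(w), sd = s)$p.value)
    } else {
      nortest::lillie.test(w)$p.value
    }
  }
  pv
}

ks_normality_sweep <- function(ts, deltas, overlaps, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  x <- as_ts_matrix(ts)
  overlaps <- rep_len(as.integer(overlaps), length(deltas))
  if (method == "lilliefors" && !requireNamespace("nortest", quietly = TRUE)) {
    abort("method = \"lilliefors\" requires the nortest package")
  }
  rows <- purrr::map2(as.integer(deltas), overlaps, function(delta, ov) {
    win <- make_windows(nrow(x), delta, ov)
    if (win$n_windows < 5L) {
      abort(sprintf("window size %d yields only %d windows; need at least 5", delta, win$n_windows))
    }
    dfc <- rescale_minmax(windowed_correlation(x, win), scope = "global")
    pv <- pair_normality_pvalues(dfc, method)
    skipped <- sum(is.na(pv))
    if (skipped > 0L) {
      inform(sprintf("window size %d: skipped %d zero-variance pair(s)", delta, skipped))
    }
    tibble::tibble(
      delta = delta, overlap = ov, tau = win$n_windows,
      mean_pvalue = mean(pv, na.rm = TRUE),
      n_pairs = sum(!is.na(pv)), n_skipped = skipped,
      pvalues = list(pv)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("normality_report", class(out))
  out
}

#' Mean percentage error between two network matrices
#'
#' `100 * mean(|x_ij - y_ij|) / max(mean(|y_ij|), eps)` over off-diagonal
#' cells: the cellwise absolute difference normalized by the reference
#' matrix's mean absolute off-diagonal value. The normalization makes the
#' measure invariant to a common positive rescaling of both matrices and
#' well-defined for sparse binary backbones (a cellwise ratio would divide
#' by zero); the reference is the second argument.
#'
#' @param x,y Square matrices of equal size; `y` is the reference.
#' @param eps Floor on the normalizer (default `1e-12`).
#' @return The MPE as a percentage (0 when `x == y`).
#' @export
mpe <- function(x, y, eps = 1e-12) {
  check_square(x, arg = "x")
  check_square(y, nrow(x), "y")
  mask <- off_diag(nrow(x))
  num <- mean(abs(x[mask] - y[mask]))
  if (num == 0) return(0)
  100 * num / max(mean(abs(y[mask])), eps)
}

#' Backbone stability across window sizes
#'
#' Runs the full backbone pipeline (windowing, correlation, rescaling, latent
#' fit, percentile filter) once per window size and percentile threshold, and
#' reports the pairwise mean percentage error between the resulting binary
#' backbones. Unlike the raw [mpe()], whose normalizer is its second
#' (reference) argument, the pairwise comparison normalizes by the average of
#' both matrices' mean absolute off-diagonal values, so the reported matrix
#' of errors is symmetric with a zero diagonal.
#'
#' @param ts Time series (data frame or matrix).
#' @param deltas Window sizes to compare.
#' @param overlaps Overlaps, recycled against `deltas`.
#' @param thresholds Percentile thresholds `c` (so `alpha = 1 - c`);
#'   default `c(0.5, 0.9)`.
#' @param count_fraction Aggregation fraction, default 0.5.
#' @return A tibble with columns `threshold_c`, `delta_x`, `delta_y`, `mpe`,
#'   covering all ordered pairs of window sizes (symmetric, zero on the
#'   diagonal).
#' @export
stability_across_windows <- function(ts, deltas, overlaps,
                                     thresholds = c(0.5, 0.9),
                                     count_fraction = 0.5) {
  x <- as_ts_matrix(ts)
  deltas <- as.integer(deltas)
  overlaps <- rep_len(as.integer(overlaps), length(deltas))
  if (any(thresholds <= 0 | thresholds >= 1)) abort("`thresholds` must be in (0, 1)")
  fits <- purrr::map2(deltas, overlaps, function(delta, ov) {
    dfc <- build_dfc(x, width = delta, overlap = ov)
    list(dfc = dfc, params = solve_latent(dfc))
  })
  purrr::map_dfr(thresholds, function(cc) {
    backbones <- purrr::map(fits, function(f) {
      cfg <- significance_config(alpha = 1 - cc, count_fraction = count_fraction)
      extract_backbone(f$dfc, params = f$params, config = cfg, weighted = FALSE)$binary
    })
    grid <- expand.grid(ix = seq_along(deltas), iy = seq_along(deltas))
    tibble::tibble(
      threshold_c = cc,
      delta_x = deltas[grid$ix],
      delta_y = deltas[grid$iy],
      mpe = purrr::map2_dbl(grid$ix, grid$iy, function(ix, iy) {
        x <- backbones[[ix]]
        y <- backbones[[iy]]
        mask <- off_diag(nrow(x))
        num <- mean(abs(x[mask] - y[mask]))
        if (num == 0) 0 else 100 * num / max((mean(abs(x[mask])) + mean(abs(y[mask]))) / 2, 1e-12)
      })
    )
  })
}

# Column-wise (univariate) AR surrogates for a matrix of pair weight
# sequences: each column gets its own least-squares AR(p) fit and M
# surrogates seeded from random blocks of its own history. Used by the
# tensor-route ARR baseline, where a full multivariate VAR across all
# P = N(N-1)/2 pair series would be unidentifiable (P >> tau).
univariate_ar_surrogates <- function(x, order, n_surrogates, seed) {
  tt <- nrow(x)
  p <- as.integer(order)
  if (tt <= 10L * p) {
    abort(sprintf("AR fit needs T > 10 * order (T=%d, order=%d)", tt, p))
  }
  fits <- lapply(seq_len(ncol(x)), function(jj) {
    v <- x[, jj]
    mu <- mean(v)
    vc <- v - mu
    y <- vc[(p + 1L):tt]
    design <- vapply(seq_len(p), function(l) vc[(p + 1L - l):(tt - l)], numeric(tt - p))
    fit <- stats::lm.fit(as.matrix(design), y)
    phi <- fit$coefficients
    phi[is.na(phi)] <- 0
    list(mu = mu, phi = phi, sd = sqrt(mean(fit$residuals^2)), vc = vc)
  })
  withr::with_seed(seed, {
    lapply(seq_len(n_surrogates), function(m) {
      out <- matrix(0, tt, ncol(x))
      for (jj in seq_len(ncol(x))) {
        f <- fits[[jj]]
        s <- sample.int(tt - p + 1L, 1L)
        v <- numeric(tt)
        v[seq_len(p)] <- f$vc[s:(s + p - 1L)]
        innov <- stats::rnorm(tt - p, sd = f$sd)
        for (t in (p + 1L):tt) {
          v[t] <- sum(f$phi * v[(t - 1L):(t - p)]) + innov[t - p]
        }
        out[, jj] <- v + f$mu
      }
      out
    })
  })
}

# Pearson correlation with an explicit undefined marker for constant input
cor_or_undefined <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    list(estimate = NA_real_, undefined = TRUE)
  } else {
    list(estimate = stats::cor(x, y), undefined = FALSE)
  }
}

#' Correlations between latent variables, degrees and backbone structure
#'
#' Summarizes how the fitted latent propensities relate to observable network
#' quantities: (i) aggregated dynamic-connectivity node degree vs `a_i`
#' (expected strongly positive under the model), (ii) share of significant
#' ties vs `a_i` (the model's control for local strength shows up as a weak,
#' typically negative, relation), (iii) backbone node degree vs `a_i` and
#' `b_i`, and (iv) per-pair time-mean weight vs backbone value. Constant
#' vectors yield an explicit `undefined` marker instead of `NaN`.
#'
#' @param dfc A [dfc_tensor()].
#' @param params Fitted [latent_params()].
#' @param backbone A `backbone_result` for the same tensor.
#' @return A tibble with columns `metric`, `correlation`, `undefined`.
#' @export
latent_degree_correlation <- function(dfc, params, backbone) {
  stopifnot(inherits(dfc, "dfc_tensor"), inherits(params, "latent_params"),
            inherits(backbone, "backbone_result"))
  n <- n_nodes(dfc)
  if (length(params$a) != n || nrow(backbone$binary) != n) {
    abort("`dfc`, `params` and `backbone` disagree on the node count")
  }
  wbar <- dfc_time_mean(dfc)
  dfc_degree <- rowSums(wbar) * n_windows_of(dfc) # aggregated over windows
  share <- share_significant_ties(backbone)$share
  bb_degree <- rowSums(backbone$binary)
  ut <- upper.tri(diag(n))
  bb_value <- if (is.null(backbone$weighted)) backbone$binary[ut] * 1.0 else backbone$weighted[ut]

  specs <- list(
    dfc_degree_vs_a = cor_or_undefined(dfc_degree, params$a),
    share_ties_vs_a = cor_or_undefined(share, params$a),
    backbone_degree_vs_a = cor_or_undefined(bb_degree, params$a),
    backbone_degree_vs_b = cor_or_undefined(bb_degree, params$b),
    mean_weight_vs_backbone = cor_or_undefined(wbar[ut], bb_value)
  )
  tibble::tibble(
    metric = names(specs),
    correlation = vapply(specs, function(s) s$estimate, numeric(1)),
    undefined = vapply(specs, function(s) s$undefined, logical(1))
  )
}

#' Rank-based AUC of per-pair detection scores against ground truth
#'
#' Area under the ROC curve computed by the midrank Mann-Whitney formula:
#' the probability that a uniformly chosen corrupted (injected) pair scores
#' higher than a uniformly chosen clean pair, with ties counted half.
#'
#' @param scores Per-pair scores: an `N x N` symmetric matrix or a vector
#'   aligned with the upper triangle (`i < j`, column-major).
#' @param truth A ground truth from [inject_random_links()] (its
#'   `injected_mask` is the positive class) or a logical/0-1 vector or matrix.
#' @return The AUC in `[0, 1]`.
#' @export
detection_auc <- function(scores, truth) {
  if (is.matrix(scores)) scores <- utri(scores)
  if (inherits(truth, "wbn_ground_truth")) truth <- truth$injected_mask
  if (is.matrix(truth)) truth <- utri(truth)
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) abort("`scores` and `truth` lengths differ")
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    abort("degenerate ground truth: need at least one positive and one negative pair")
  }
  r <- rank(scores) # midranks for ties
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Injected-link detection benchmark across null models
#'
#' Scores the same injected tensor through four detection routes and reports
#' each one's AUC against the injection ground truth:
#' \describe{
#'   \item{wbn}{latent-model exceedance counts from [extract_backbone()]
#'     (null fitted on the corrupted tensor, as in practice);}
#'   \item{arr, pr}{surrogate exceedance counts where the surrogates
#'     randomize each pair's temporal weight sequence: phase randomization
#'     treats the `tau x P` matrix of pair series as one multivariate series
#'     (common phases), while the autoregressive route fits one univariate
#'     AR(p) per pair sequence (a joint VAR over all pairs would be
#'     unidentifiable at `P >> tau`); a pair-window is flagged when the
#'     observed weight strictly exceeds the ensemble's `(1 - alpha)` order
#'     statistic;}
#'   \item{binarized_threshold}{temporal sums of the mean-binarized tensor
#'     ([binarize_tensor()]), the rule used to feed binary-network filters.}
#' }
#'
#' @param dfc The corrupted [dfc_tensor()].
#' @param truth Ground truth from [inject_random_links()].
#' @param alpha Significance level (default 0.2).
#' @param n_surrogates Surrogate ensemble size for ARR/PR (default 50).
#' @param seed Integer seed for the surrogate draws.
#' @param order VAR order for the ARR route.
#' @param methods Subset of the four routes to run.
#' @return A `detection_report` tibble: `method`, `auc`, `n_positive`,
#'   `n_negative`, with the per-pair score vectors in a list-column `scores`.
#' @export
detection_benchmark <- function(dfc, truth, alpha = 0.2, n_surrogates = 50L,
                                seed = 1L, order = 1L,
                                methods = c("wbn", "arr", "pr", "binarized_threshold")) {
  stopifnot(inherits(dfc, "dfc_tensor"), inherits(truth, "wbn_ground_truth"))
  methods <- match.arg(methods, several.ok = TRUE)
  n <- n_nodes(dfc)
  tau <- n_windows_of(dfc)
  ut <- upper.tri(diag(n))
  labels <- as.logical(truth$injected_mask[ut])

  score_list <- list()
  if ("wbn" %in% methods) {
    bb <- extract_backbone(dfc, config = significance_config(alpha = alpha),
                           weighted = FALSE)
    score_list$wbn <- as.numeric(bb$counts[ut])
  }
  if (any(c("arr", "pr") %in% methods)) {
    # pair weight sequences as a tau x P multivariate series
    pair_series <- t(apply(dfc$weights, 3L, function(sl) sl[ut]))
    if (sum(ut) == 1L) pair_series <- matrix(pair_series, ncol = 1L)
    colnames(pair_series) <- paste0("pair_", seq_len(ncol(pair_series)))
    m <- as.integer(n_surrogates)
    if (m * alpha < 1) abort("M * alpha < 1: too few surrogates for this alpha")
    k <- surrogate_order_stat(m, alpha)
    surrogate_counts <- function(method) {
      series <- switch(method,
        arr = univariate_ar_surrogates(pair_series, order, m, derive_seed(seed, 11L)),
        pr = generate_pr(pair_series, m, derive_seed(seed, 13L))$series
      )
      stack <- array(unlist(series), dim = c(tau, ncol(pair_series), m))
      thr <- apply(stack, c(1L, 2L), function(v) sort(v)[k])
      colSums(pair_series > thr)
    }
    if ("arr" %in% methods) score_list$arr <- as.numeric(surrogate_counts("arr"))
    if ("pr" %in% methods) score_list$pr <- as.numeric(surrogate_counts("pr"))
  }
  if ("binarized_threshold" %in% methods) {
    bin <- binarize_tensor(dfc)
    score_list$binarized_threshold <- as.numeric(apply(bin, c(1L, 2L), sum)[ut])
  }

  out <- tibble::tibble(
    method = names(score_list),
    auc = vapply(score_list, function(s) detection_auc(s, labels), numeric(1)),
    n_positive = sum(labels),
    n_negative = sum(!labels),
    scores = unname(score_list)
  )
  class(out) <- c("detection_report", class(out))
  out
}
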