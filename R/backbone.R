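#' Significance configuration for backbone extraction
#'
#' @param alpha Significance level in (0, 1); the percentile test compares
#'   each weight against the `c = (1 - alpha)` quantile of its fitted null
#'   (so `alpha = 0.2` means the 80th percentile). Default 0.2.
#' @param count_fraction Fraction of windows a pair must exceed its threshold
#'   in (strictly) to enter the backbone; default 0.5, i.e. `count > tau/2`.
#' @param correction Multiple-testing adjustment of `alpha`: `"none"`
#'   (default), `"bonferroni_count"` (divide by the number of tested pairs,
#'   `N(N-1)/2`, the conventional choice), or `"bonferroni_weight_sum"`
#'   (divide by the total summed edge weight; a nonstandard variant kept for
#'   completeness — a warning notes that the two differ).
#'
#' @return A `significance_config` object.
#' @export
significance_config <- function(alpha = 0.2, count_fraction = 0.5,
                                correction = c("none", "bonferroni_count", "bonferroni_weight_sum")) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1)")
  }
  if (!is.numeric(count_fraction) || length(count_fraction) != 1L ||
      count_fraction <= 0 || count_fraction >= 1) {
    abort("`count_fraction` must be a single number in (0, 1)")
  }
  if (correction == "bonferroni_weight_sum") {
    warn(paste(
      "bonferroni_weight_sum divides alpha by the total summed edge weight;",
      "this differs from the conventional count-based Bonferroni divisor"
    ))
  }
  structure(
    list(alpha = alpha, count_fraction = count_fraction, correction = correction),
    class = "significance_config"
  )
}

#' @export
print.significance_config <- function(x, ...) {
  cat(sprintf(
    "<significance_config> alpha=%g (c=%g percentile), count_fraction=%g, correction=%s\n",
    x$alpha, 100 * (1 - x$alpha), x$count_fraction, x$correction
  ))
  invisible(x)
}

# alpha after the configured multiple-testing adjustment
effective_alpha <- function(config, dfc = NULL) {
  switch(config$correction,
    none = config$alpha,
    bonferroni_count = {
      n <- n_nodes(dfc)
      config$alpha / (n * (n - 1) / 2)
    },
    bonferroni_weight_sum = {
      total <- sum(vapply(seq_len(n_windows_of(dfc)),
                          function(t) sum(utri(dfc$weights[, , t])), numeric(1)))
      if (total <= 0) abort("total edge weight is zero; weight-sum correction undefined")
      config$alpha / total
    }
  )
}

#' Per-pair significance thresholds of the fitted null
#'
#' The threshold for pair `(i, j)` is the `(1 - alpha)` quantile of its fitted
#' Gaussian, `mu_ij + sigma_ij * z_{1 - alpha}`. Thresholds are constant
#' across windows because the null is stationary by construction.
#'
#' @param dist A [pair_distributions()] object.
#' @param alpha Upper-tail significance level in (0, 1).
#' @return An `N x N` symmetric matrix of thresholds.
#' @export
percentile_threshold <- function(dist, alpha) {
  stopifnot(inherits(dist, "pair_null"))
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  dist$mu + dist$sigma * stats::qnorm(1 - alpha)
}

#' Upper-tail p value of a link weight under its fitted null
#'
#' `p = 1 - Phi((w - mu) / sigma)`: the probability that the null Gaussian
#' produces a weight at least as large as the observed one. Only the upper
#' tail is tested — a tie is significant when its weight is too large for the
#' null, never too small.
#'
#' @param w Observed weight(s).
#' @param mu,sigma Null mean(s) and standard deviation(s); `sigma > 0`.
#'   All arguments recycle.
#' @return p value(s) in `[0, 1]`.
#' @export
link_pvalue <- function(w, mu, sigma) {
  if (any(sigma <= 0)) abort("`sigma` must be strictly positive")
  stats::pnorm((w - mu) / sigma, lower.tail = FALSE)
}

#' Per-window exceedance flags and counts
#'
#' Flags window `t` of pair `(i, j)` when `w_ijt` strictly exceeds that pair's
#' percentile threshold, and accumulates per-pair exceedance counts over the
#' `tau` windows. Flagging is exactly coherent with [link_pvalue()]:
#' a cell is flagged iff its p value is below the (corrected) alpha.
#'
#' @param dfc A [dfc_tensor()].
#' @param dist The pair's fitted null, from [pair_distributions()].
#' @param config A [significance_config()].
#' @return A `wbn_flags` object: `flags` (`N x N x tau` 0/1 array), `counts`
#'   (`N x N` integer matrix), `thresholds`, `pvals` (`N x N x tau`), and the
#'   effective alpha after correction.
#' @export
flag_windows <- function(dfc, dist, config = significance_config()) {
  stopifnot(inherits(dfc, "dfc_tensor"), inherits(dist, "pair_null"))
  n <- n_nodes(dfc)
  check_square(dist$mu, n, "dist$mu")
  tau <- n_windows_of(dfc)
  a_eff <- effective_alpha(config, dfc)
  thr <- percentile_threshold(dist, a_eff)
  mask <- off_diag(n)
  flags <- array(0L, dim = dim(dfc$weights), dimnames = dimnames(dfc$weights))
  pvals <- array(NA_real_, dim = dim(dfc$weights), dimnames = dimnames(dfc$weights))
  counts <- matrix(0L, n, n, dimnames = dimnames(dfc$weights)[1:2])
  for (t in seq_len(tau)) {
    w <- dfc$weights[, , t]
    fl <- matrix(0L, n, n)
    fl[mask] <- as.integer(w[mask] > thr[mask])
    flags[, , t] <- fl
    counts <- counts + fl
    p <- matrix(NA_real_, n, n)
    p[mask] <- link_pvalue(w[mask], dist$mu[mask], dist$sigma[mask])
    pvals[, , t] <- p
  }
  structure(
    list(flags = flags, counts = counts, thresholds = thr, pvals = pvals,
         alpha_effective = a_eff, config = config, tau = tau),
    class = "wbn_flags"
  )
}

#' Aggregate exceedance counts into the binary backbone
#'
#' A pair enters the backbone iff its exceedance count is strictly above
#' `count_fraction * tau` (by default, strictly above half the windows;
#' at even `tau`, a count of exactly `tau/2` is rejected).
#'
#' @param counts `N x N` integer matrix of per-pair exceedance counts.
#' @param tau Number of temporal windows.
#' @param config A [significance_config()].
#' @return An `N x N` 0/1 integer matrix (symmetric, zero diagonal).
#' @export
aggregate_backbone <- function(counts, tau, config = significance_config()) {
  check_square(counts, arg = "counts")
  if (any(counts < 0 | counts > tau)) abort("`counts` must lie in [0, tau]")
  binary <- matrix(as.integer(counts > config$count_fraction * tau),
                   nrow(counts), dimnames = dimnames(counts))
  diag(binary) <- 0L
  binary
}

#' Weighted backbone from threshold exceedances
#'
#' For admitted pairs, the backbone weight is the temporal mean of the
#' difference between the observed weight and the pair's threshold
#' (`signed_mean`; windows below threshold contribute negatively), or the
#' mean of the positive part only (`positive_mean`). Non-admitted pairs get 0.
#'
#' @param dfc A [dfc_tensor()].
#' @param thresholds `N x N` threshold matrix from [percentile_threshold()].
#' @param binary `N x N` 0/1 admission matrix from [aggregate_backbone()].
#' @param measure `"signed_mean"` (default) or `"positive_mean"`.
#' @return An `N x N` numeric matrix.
#' @export
weighted_backbone <- function(dfc, thresholds, binary,
                              measure = c("signed_mean", "positive_mean")) {
  measure <- match.arg(measure)
  stopifnot(inherits(dfc, "dfc_tensor"))
  n <- n_nodes(dfc)
  check_square(thresholds, n, "thresholds")
  check_square(binary, n, "binary")
  tau <- n_windows_of(dfc)
  acc <- matrix(0, n, n)
  for (t in seq_len(tau)) {
    d <- dfc$weights[, , t] - thresholds
    if (measure == "positive_mean") d <- pmax(d, 0)
    acc <- acc + d
  }
  out <- (acc / tau) * (binary == 1L)
  diag(out) <- 0
  dimnames(out) <- dimnames(binary)
  out
}

#' Extract the backbone network of a dynamic-connectivity tensor
#'
#' End-to-end filtering step: fits (or accepts) the latent null, thresholds
#' every pair in every window at the null's upper `(1 - alpha)` percentile,
#' and admits pairs exceeding the threshold in more than
#' `count_fraction * tau` windows.
#'
#' @param dfc A [dfc_tensor()].
#' @param params Optional [latent_params()]; fitted with [solve_latent()]
#'   when omitted.
#' @param config A [significance_config()].
#' @param weighted Also compute the weighted backbone variant? Default TRUE.
#' @param measure Weighted-variant measure, see [weighted_backbone()].
#'
#' @return A `backbone_result` with fields `counts`, `binary`, `weighted`,
#'   `pvals`, `thresholds`, `params`, `config`, `tau`.
#' @examples
#' sim <- simulate_null_tensor(synthetic_spec(n_nodes = 12, tau = 40, seed = 3))
#' bb <- extract_backbone(sim$dfc)
#' glance(bb)
#' @export
extract_backbone <- function(dfc, params = NULL, config = significance_config(),
                             weighted = TRUE, measure = "signed_mean") {
  stopifnot(inherits(dfc, "dfc_tensor"))
  params <- params %||% solve_latent(dfc)
  dist <- pair_distributions(params)
  fl <- flag_windows(dfc, dist, config)
  binary <- aggregate_backbone(fl$counts, fl$tau, config)
  wb <- if (weighted) weighted_backbone(dfc, fl$thresholds, binary, measure) else NULL
  structure(
    list(
      counts = fl$counts, binary = binary, weighted = wb, pvals = fl$pvals,
      thresholds = fl$thresholds, alpha_effective = fl$alpha_effective,
      params = params, config = config, tau = fl$tau,
      node_labels = dfc$node_labels
    ),
    class = "backbone_result"
  )
}

#' @export
print.backbone_result <- function(x, ...) {
  n <- nrow(x$binary)
  cat(sprintf(
    "<backbone_result> %d nodes, tau=%d | alpha=%g (%s) | %d / %d pairs admitted\n",
    n, x$tau, x$config$alpha, x$config$correction,
    sum(utri(x$binary)), n * (n - 1) / 2
  ))
  invisible(x)
}

#' @describeIn extract_backbone One row per unordered pair: exceedance count,
#'   admission, weighted value and median per-window p value.
#' @param x A `backbone_result`.
#' @param ... Unused.
#' @export
#' @method tidy backbone_result
tidy.backbone_result <- function(x, ...) {
  n <- nrow(x$binary)
  pairs <- upper_pairs(n)
  ut <- upper.tri(diag(n))
  med_p <- apply(x$pvals, c(1L, 2L), stats::median)
  tibble::tibble(
    node_i = x$node_labels[pairs$i],
    node_j = x$node_labels[pairs$j],
    count = as.integer(x$counts[ut]),
    admitted = x$binary[ut] == 1L,
    weight = if (is.null(x$weighted)) NA_real_ else x$weighted[ut],
    threshold = x$thresholds[ut],
    median_pvalue = med_p[ut]
  )
}

#' @describeIn extract_backbone One-row summary of the filtering run.
#' @export
#' @method glance backbone_result
glance.backbone_result <- function(x, ...) {
  n <- nrow(x$binary)
  n_pairs <- n * (n - 1) / 2
  tibble::tibble(
    n_nodes = n,
    tau = x$tau,
    alpha = x$config$alpha,
    alpha_effective = x$alpha_effective,
    count_fraction = x$config$count_fraction,
    correction = x$config$correction,
    n_admitted = sum(utri(x$binary)),
    density = sum(utri(x$binary)) / n_pairs
  )
}

#' Share of significant ties per node
#'
#' The fraction of a node's possible ties that are admitted to the backbone:
#' its backbone degree divided by `N - 1`.
#'
#' @param x A `backbone_result` or a symmetric 0/1 matrix with zero diagonal.
#' @return A tibble with columns `node` and `share`.
#' @export
share_significant_ties <- function(x) {
  if (inherits(x, "backbone_result")) {
    binary <- x$binary
    labels <- x$node_labels
  } else {
    binary <- check_square(x, arg = "x")
    if (any(diag(binary) != 0)) abort("binary backbone must have zero diagonal")
    labels <- rownames(binary) %||% paste0("node_", seq_len(nrow(binary)))
  }
  tibble::tibble(node = labels, share = rowSums(binary) / (nrow(binary) - 1))
}

#' Group consensus of binary backbones
#'
#' Cellwise mean of per-subject binary backbones: the fraction of subjects in
#' which each tie is admitted. A display copy additionally zeroes entries
#' below `display_floor` (presentation filter only; the full consensus is
#' kept unaltered).
#'
#' @param backbones List of `backbone_result`s or binary matrices of equal size.
#' @param display_floor Entries below this value are zeroed in the display
#'   copy (default 0.05).
#' @return A `wbn_consensus` object with fields `mean`, `display`,
#'   `n_subjects`, `display_floor`.
#' @export
group_consensus <- function(backbones, display_floor = 0.05) {
  if (length(backbones) == 0L) abort("`backbones` must contain at least one backbone")
  mats <- lapply(backbones, function(b) {
    if (inherits(b, "backbone_result")) b$binary else check_square(b, arg = "backbones[[.]]")
  })
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1)))) {
    abort("all backbones must have the same dimensions")
  }
  cons <- Reduce(`+`, lapply(mats, function(m) m * 1.0)) / length(mats)
  display <- cons
  display[display < display_floor] <- 0
  structure(
    list(mean = cons, display = display, n_subjects = length(mats),
         display_floor = display_floor),
    class = "wbn_consensus"
  )
}

#' @export
print.wbn_consensus <- function(x, ...) {
  cat(sprintf(
    "<wbn_consensus> %d subjects, %d nodes | %d ties above display floor %g\n",
    x$n_subjects, nrow(x$mean), sum(utri(x$display) > 0), x$display_floor
  ))
  invisible(x)
}

#' @describeIn group_consensus One row per unordered pair with consensus and
#'   display values.
#' @param x A `wbn_consensus`.
#' @param ... Unused.
#' @export
#' @method tidy wbn_consensus
tidy.wbn_consensus <- function(x, ...) {
  n <- nrow(x$mean)
  labels <- rownames(x$mean) %||% paste0("node_", seq_len(n))
  pairs <- upper_pairs(n)
  ut <- upper.tri(diag(n))
  tibble::tibble(
    node_i = labels[pairs$i],
    node_j = labels[pairs$j],
    consensus = x$mean[ut],
    display = x$display[ut]
  )
}
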