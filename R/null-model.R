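#' Latent parameters of the Gaussian temporal null model
#'
#' Under the null model every node `i` carries two latent propensities
#' `a_i, b_i` in `(0, 1]`, and the weights of the tie between `i` and `j`
#' over the `tau` windows are i.i.d. Gaussian with mean `a_i * a_j` and
#' standard deviation `b_i * b_j`. This constructor is mostly internal;
#' fitted values come from [solve_latent()] or [init_params()].
#'
#' @param a,b Positive numeric vectors of length N. Values above 1 are
#'   permitted but flagged with a warning (the model states `(0, 1]`).
#' @param node_labels Character vector of node labels.
#' @param residual_norm Max-norm of the stacked estimating-equation residuals
#'   at these parameters.
#' @param converged,iterations,solver_name Solver diagnostics.
#'
#' @return A `latent_params` object.
#' @export
latent_params <- function(a, b, node_labels = NULL, residual_norm = NA_real_,
                          converged = NA, iterations = NA_integer_,
                          solver_name = "manual") {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) abort("`a` and `b` must have the same length")
  if (any(a <= 0) || any(b <= 0)) abort("latent parameters must be strictly positive")
  if (any(a > 1) || any(b > 1)) {
    warn(sprintf(
      "%d latent value(s) exceed 1; the null model states a_i, b_i in (0, 1]",
      sum(a > 1) + sum(b > 1)
    ))
  }
  node_labels <- node_labels %||% paste0("node_", seq_along(a))
  structure(
    list(
      a = a, b = b, node_labels = as.character(node_labels),
      residual_norm = residual_norm, converged = converged,
      iterations = as.integer(iterations), solver_name = solver_name
    ),
    class = "latent_params"
  )
}

#' @export
print.latent_params <- function(x, ...) {
  cat(sprintf(
    "<latent_params> %d nodes | solver: %s | residual max-norm: %.3g | converged: %s\n",
    length(x$a), x$solver_name, x$residual_norm, x$converged
  ))
  invisible(x)
}

#' @describeIn latent_params One row per node with fitted `a` and `b`.
#' @param x A `latent_params` object.
#' @param ... Unused.
#' @export
#' @method tidy latent_params
tidy.latent_params <- function(x, ...) {
  tibble::tibble(node = x$node_labels, a = x$a, b = x$b)
}

#' @describeIn latent_params One-row solver summary.
#' @export
#' @method glance latent_params
glance.latent_params <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$a),
    residual_norm = x$residual_norm,
    converged = x$converged,
    iterations = x$iterations,
    solver = x$solver_name
  )
}

# per-pair mean squared deviation about mu = outer(a, a), with /tau divisor
pair_msd <- function(weights, mu) {
  tau <- dim(weights)[3L]
  n <- dim(weights)[1L]
  acc <- matrix(0, n, n)
  for (t in seq_len(tau)) acc <- acc + (weights[, , t] - mu)^2
  acc / tau
}

#' Log-likelihood of the Gaussian temporal null
#'
#' Evaluates the model log-likelihood of a dynamic-connectivity tensor at
#' given latent parameters: the sum over unordered pairs `i < j` of
#' `-tau * log(b_i b_j) - tau/2 * log(2 pi) - sum_t (w_ijt - a_i a_j)^2 /
#' (2 (b_i b_j)^2)`. (Summing ordered pairs would double every term and not
#' move the optimum; unordered pairs are used throughout.)
#'
#' @param dfc A [dfc_tensor()].
#' @param params A [latent_params()] with strictly positive entries.
#' @return The scalar log-likelihood.
#' @export
loglikelihood <- function(dfc, params) {
  stopifnot(inherits(dfc, "dfc_tensor"), inherits(params, "latent_params"))
  if (any(params$a <= 0) || any(params$b <= 0)) abort("parameters must be strictly positive")
  n <- n_nodes(dfc)
  if (length(params$a) != n) abort("parameter length does not match node count")
  tau <- n_windows_of(dfc)
  mu <- outer(params$a, params$a)
  sig <- outer(params$b, params$b)
  q <- pair_msd(dfc$weights, mu) * tau # sum_t (w - mu)^2
  ll <- -tau * log(sig) - tau / 2 * log(2 * pi) - q / (2 * sig^2)
  sum(ll[upper.tri(ll)])
}

#' Degree-based initialization of the latent parameters
#'
#' Initializes `a_i` as the node's time-averaged weighted degree divided by
#' twice the total time-averaged edge weight, so that `sum(a) = 1` before
#' clipping. `b_i` is initialized by the same degree normalization applied to
#' the per-pair empirical temporal standard deviations. Both vectors are
#' clipped into `[1e-6, 1]`.
#'
#' @param dfc A [dfc_tensor()].
#' @return A [latent_params()] with `solver_name = "init"`.
#' @export
init_params <- function(dfc) {
  stopifnot(inherits(dfc, "dfc_tensor"))
  wbar <- dfc_time_mean(dfc)
  total <- sum(utri(wbar))
  if (total <= 0) abort("degenerate input: total summed weight is zero")
  a0 <- rowSums(wbar) / (2 * total)

  tau <- n_windows_of(dfc)
  emp_mean <- wbar
  sd_pair <- sqrt(pair_msd(dfc$weights, emp_mean)) # population SD (divisor tau)
  tot_sd <- sum(utri(sd_pair))
  if (tot_sd > 0) {
    b0 <- rowSums(sd_pair) / (2 * tot_sd)
  } else {
    b0 <- rep(1e-6, length(a0))
  }
  clip <- function(v) pmin(pmax(v, 1e-6), 1)
  p <- latent_params(clip(a0), clip(b0), node_labels = dfc$node_labels,
                     converged = FALSE, iterations = 0L, solver_name = "init")
  p$residual_norm <- max(abs(estimating_equations(dfc, p)))
  p
}

#' Estimating-equation residuals of the null model
#'
#' Stacks the two blocks of first-order conditions. For each node `i`, the
#' mean block is `sum_{j != i} (a_i a_j - wbar_ij)` with `wbar_ij` the
#' time-mean weight; the spread block is
#' `sum_{j != i} (-(b_i b_j)^2 + sum_t (w_ijt - a_i a_j)^2 / tau)`.
#' A fitted model drives the max-norm of this vector to the solver tolerance.
#'
#' @inheritParams loglikelihood
#' @return Numeric vector of length `2N` (mean block first).
#' @export
estimating_equations <- function(dfc, params) {
  stopifnot(inherits(dfc, "dfc_tensor"), inherits(params, "latent_params"))
  if (any(params$a <= 0) || any(params$b <= 0)) abort("parameters must be strictly positive")
  a <- params$a
  b <- params$b
  wbar <- dfc_time_mean(dfc)
  mu <- outer(a, a)
  diff_a <- mu - wbar
  diag(diff_a) <- 0
  r_a <- rowSums(diff_a)

  v <- pair_msd(dfc$weights, mu)
  beta <- b^2
  diff_b <- v - outer(beta, beta)
  diag(diff_b) <- 0
  r_b <- rowSums(diff_b)
  unname(c(r_a, r_b))
}

#' Fit the latent null model by solving the estimating equations
#'
#' Solves the `2N` nonlinear first-order conditions in two stages, mirroring
#' the model's own sequencing: the mean block (which does not involve `b`) is
#' solved first for `a`, then the spread block is solved for `b` with `a`
#' fixed. Each block reduces to the same product-moment system and is solved
#' by a damped Newton iteration in log-parameterization (which enforces
#' positivity); see the methods vignette for the numerical details.
#'
#' @param dfc A [dfc_tensor()] with at least 3 nodes.
#' @param tol Convergence tolerance on the max-norm of the stacked residuals.
#' @param max_iter Maximum Newton iterations per block.
#'
#' @return A [latent_params()] with solver diagnostics. On non-convergence the
#'   best iterate is returned with `converged = FALSE` and a warning.
#' @examples
#' sim <- simulate_null_tensor(synthetic_spec(n_nodes = 10, tau = 100, seed = 1))
#' fit <- solve_latent(sim$dfc)
#' tidy(fit)
#' @export
solve_latent <- function(dfc, tol = 1e-10, max_iter = 500L) {
  stopifnot(inherits(dfc, "dfc_tensor"))
  init <- suppressWarnings(init_params(dfc))
  wbar <- dfc_time_mean(dfc)

  sol_a <- solve_product_system(wbar, init$a, tol = tol, max_iter = max_iter)
  a <- sol_a$x

  mu <- outer(a, a)
  v <- pair_msd(dfc$weights, mu)
  if (all(utri(v) <= 0)) {
    # all pairs have zero temporal variance about the fitted means
    beta <- rep(1e-10, length(a))
    sol_b <- list(iterations = 0L, converged = TRUE)
  } else {
    beta0 <- pmin(pmax(init$b, 1e-6), 1)^2
    sol_b <- solve_product_system(v, beta0, tol = tol, max_iter = max_iter)
    beta <- sol_b$x
  }
  b <- sqrt(beta)

  p <- latent_params(a, b, node_labels = dfc$node_labels,
                     iterations = sol_a$iterations + sol_b$iterations,
                     solver_name = "newton_log")
  res <- estimating_equations(dfc, p)
  if (any(!is.finite(res))) abort("non-finite estimating-equation residuals at the solution")
  p$residual_norm <- max(abs(res))
  p$converged <- p$residual_norm <= tol
  if (!p$converged) {
    warn(sprintf(
      "latent solver did not reach tol=%.1g (residual max-norm %.3g after %d iterations); returning best iterate",
      tol, p$residual_norm, p$iterations
    ))
  }
  p
}

#' Direct maximization of the null-model likelihood
#'
#' Labeled alternative estimator: maximizes the exact log-likelihood
#' ([loglikelihood()]) over `log(a), log(b)` with `optim()` (BFGS with an
#' analytic gradient). The estimating equations solved by [solve_latent()]
#' are moment conditions that coincide with the exact score in homogeneous
#' networks but not in general; this estimator is the cross-check for that
#' distinction and is practical for small N.
#'
#' @inheritParams solve_latent
#' @param init Optional starting [latent_params()]; defaults to [init_params()].
#' @param maxit Maximum optimizer iterations.
#' @return A [latent_params()] with `solver_name = "direct_ml"`. Its
#'   `residual_norm` is still reported against the moment equations for
#'   comparability.
#' @export
fit_latent_direct <- function(dfc, init = NULL, maxit = 2000L) {
  stopifnot(inherits(dfc, "dfc_tensor"))
  n <- n_nodes(dfc)
  tau <- n_windows_of(dfc)
  init <- init %||% suppressWarnings(init_params(dfc))
  w <- dfc$weights
  ut <- upper.tri(diag(n))

  negll <- function(theta) {
    a <- exp(theta[seq_len(n)])
    b <- exp(theta[n + seq_len(n)])
    mu <- outer(a, a)
    sig <- outer(b, b)
    q <- pair_msd(w, mu) * tau
    ll <- -tau * log(sig) - tau / 2 * log(2 * pi) - q / (2 * sig^2)
    -sum(ll[ut])
  }
  grad <- function(theta) {
    a <- exp(theta[seq_len(n)])
    b <- exp(theta[n + seq_len(n)])
    mu <- outer(a, a)
    sig <- outer(b, b)
    # sum_t (w - mu) and sum_t (w - mu)^2 per pair
    s1 <- apply(w, c(1L, 2L), sum) - tau * mu
    s2 <- pair_msd(w, mu) * tau
    # d(-ll)/d a_i = -sum_{j != i} s1_ij a_j / sig_ij^2
    m_a <- s1 / sig^2
    diag(m_a) <- 0
    g_a <- -as.vector(m_a %*% a)
    # d(-ll)/d b_i = sum_{j != i} [ tau / b_i - s2_ij / (sig_ij^2 b_i) ]
    m_b <- s2 / sig^2
    diag(m_b) <- 0
    g_b <- ((n - 1) * tau - rowSums(m_b)) / b
    # chain rule to log scale
    c(g_a * a, g_b * b)
  }
  theta0 <- log(pmax(c(init$a, init$b), 1e-8))
  fit <- stats::optim(theta0, negll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  a <- exp(fit$par[seq_len(n)])
  b <- exp(fit$par[n + seq_len(n)])
  p <- latent_params(a, b, node_labels = dfc$node_labels,
                     converged = fit$convergence == 0L,
                     iterations = as.integer(fit$counts[["function"]]),
                     solver_name = "direct_ml")
  p$residual_norm <- max(abs(estimating_equations(dfc, p)))
  p
}

#' Pairwise null distributions implied by latent parameters
#'
#' Builds the `N x N` matrices of null means `mu_ij = a_i a_j` and standard
#' deviations `sigma_ij = b_i b_j`; `sigma` is floored at `eps` so degenerate
#' (zero-variance) pairs keep a proper, if vanishingly narrow, Gaussian.
#' Diagonals are unused by every downstream operation.
#'
#' @param params A [latent_params()].
#' @param eps Lower floor on `sigma_ij` (default `1e-12`).
#' @return A `pair_null` object with fields `mu` and `sigma`.
#' @export
pair_distributions <- function(params, eps = 1e-12) {
  stopifnot(inherits(params, "latent_params"))
  if (any(params$a <= 0) || any(params$b <= 0)) abort("parameters must be strictly positive")
  mu <- outer(params$a, params$a)
  sigma <- pmax(outer(params$b, params$b), eps)
  dimnames(mu) <- dimnames(sigma) <- list(params$node_labels, params$node_labels)
  structure(
    list(mu = mu, sigma = sigma, node_labels = params$node_labels, eps = eps),
    class = "pair_null"
  )
}

#' @export
print.pair_null <- function(x, ...) {
  cat(sprintf(
    "<pair_null> %d nodes | mu in [%.4g, %.4g] | sigma in [%.4g, %.4g] (off-diagonal)\n",
    nrow(x$mu), min(utri(x$mu)), max(utri(x$mu)), min(utri(x$sigma)), max(utri(x$sigma))
  ))
  invisible(x)
}
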