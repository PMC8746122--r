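# Newton/Levenberg-Marquardt solver for the product-moment system shared by
# both latent blocks.
#
# Both blocks of the estimating equations have the same algebraic shape:
# find x > 0 (length N) such that, for every i,
#   r_i(x) = sum_{j != i} (x_i x_j - M_ij) = x_i (S - x_i) - d_i = 0,
# with S = sum(x) and d_i = sum_{j != i} M_ij. The mean block uses x = a and
# M = time-mean weights; the spread block uses x = b^2 and M = the per-pair
# mean squared deviations about the fitted means. Positivity is enforced by
# iterating in log(x). A full Newton step with the analytic Jacobian is tried
# first (quadratic convergence near the root); when it fails to reduce the
# residual sum of squares — typically because the Jacobian is ill-conditioned
# far from the root — the step falls back to Levenberg-Marquardt damping,
# which is a guaranteed descent direction for 0.5 * ||r||^2.
solve_product_system <- function(target, x0, tol = 1e-10, max_iter = 500L) {
  m <- target
  diag(m) <- 0
  d <- rowSums(m)
  n <- length(d)
  stopifnot(length(x0) == n)

  resid <- function(x) {
    s <- sum(x)
    x * (s - x) - d
  }

  floor_x <- 1e-10
  run_from <- function(x0) solve_ps_single(x0, resid, d, n, tol, max_iter, floor_x)
  # the damped iteration can park in a local minimum of ||r||^2 from an
  # unlucky start; a homogeneous and a degree-proportional restart cover that
  s_hom <- sqrt(max(mean(d), 1e-12) / max(n - 1, 1))
  starts <- list(
    x0,
    rep(s_hom, n),
    pmax(d, 1e-8) / sqrt(max(sum(d), 1e-12))
  )
  best <- NULL
  for (st in starts) {
    out <- run_from(st)
    if (is.null(best) || out$residual_norm < best$residual_norm) best <- out
    if (best$converged) break
  }
  best
}

solve_ps_single <- function(x0, resid, d, n, tol, max_iter, floor_x) {
  x <- pmax(x0, floor_x)
  y <- log(x)
  r <- resid(x)
  f <- max(abs(r))
  ssq <- sum(r^2)
  iter <- 0L
  lambda <- 1e-4
  while (f > tol && iter < max_iter) {
    s <- sum(x)
    jac <- matrix(rep(x, times = n), n, n) # jac[i, k] = x_i for k != i
    diag(jac) <- s - 2 * x
    jac_y <- jac * rep(x, each = n) # chain rule: columns scaled by x_k
    grad <- drop(crossprod(jac_y, r))
    if (max(abs(grad)) < 1e-14) break # stationary point of ||r||^2

    try_step <- function(step) {
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      damp <- 1
      for (k in 1:30) {
        y_new <- pmax(y + damp * step, log(floor_x))
        x_new <- exp(y_new)
        r_new <- resid(x_new)
        ssq_new <- sum(r_new^2)
        if (is.finite(ssq_new) && ssq_new < ssq) {
          return(list(y = y_new, x = x_new, r = r_new, ssq = ssq_new))
        }
        damp <- damp / 2
      }
      NULL
    }

    upd <- try_step(tryCatch(solve(jac_y, -r), error = function(e) NULL))
    if (!is.null(upd)) {
      lambda <- max(lambda / 10, 1e-12)
    } else {
      jtj <- crossprod(jac_y)
      scale <- mean(diag(jtj))
      repeat {
        lm_step <- tryCatch(solve(jtj + lambda * scale * diag(n), -grad),
                            error = function(e) NULL)
        upd <- try_step(lm_step)
        if (!is.null(upd) || lambda > 1e12) break
        lambda <- lambda * 10
      }
      if (is.null(upd)) break
    }
    y <- upd$y
    x <- upd$x
    r <- upd$r
    ssq <- upd$ssq
    f <- max(abs(r))
    iter <- iter + 1L
  }
  list(x = x, residual = r, residual_norm = f, iterations = iter, converged = f <= tol)
}
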