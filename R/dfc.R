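#' Dynamic-connectivity tensor
#'
#' Container for `tau` stacked `N x N` symmetric weight matrices (one weighted
#' graph per temporal window, zero diagonal). Produced by [rescale_minmax()] /
#' [build_dfc()] or by the synthetic generator [simulate_null_tensor()].
#'
#' @param weights `N x N x tau` numeric array; every slice must be symmetric
#'   with zero diagonal.
#' @param node_labels Optional character vector of N node labels.
#' @param windows Optional [make_windows()] spec the tensor was built from.
#' @param rescale_bounds Optional `c(min, max)` recorded by [rescale_minmax()].
#' @param scope Rescaling scope (`"global"` or `"per_window"`), if any.
#'
#' @return A `dfc_tensor` object.
#' @export
dfc_tensor <- function(weights, node_labels = NULL, windows = NULL,
                       rescale_bounds = NULL, scope = NULL) {
  if (!is.array(weights) || length(dim(weights)) != 3L) {
    abort("`weights` must be an N x N x tau array")
  }
  d <- dim(weights)
  if (d[1L] != d[2L]) abort("tensor slices must be square")
  if (d[1L] < 3L) abort("need at least 3 nodes")
  if (d[3L] < 1L) abort("need at least 1 window")
  if (any(!is.finite(weights))) abort("tensor weights must be finite")
  for (t in seq_len(d[3L])) {
    sl <- weights[, , t]
    if (any(diag(sl) != 0)) abort(sprintf("window %d has nonzero diagonal (self links must be removed)", t))
    if (max(abs(sl - t(sl))) > 1e-8) abort(sprintf("window %d slice is not symmetric", t))
  }
  attr(weights, "windows") <- NULL # provenance lives in the object, not the array
  node_labels <- node_labels %||% dimnames(weights)[[1L]] %||% paste0("node_", seq_len(d[1L]))
  if (length(node_labels) != d[1L] || anyDuplicated(node_labels)) {
    abort("`node_labels` must be unique and match the node count")
  }
  dimnames(weights) <- list(node_labels, node_labels, NULL)
  structure(
    list(
      weights = weights,
      node_labels = as.character(node_labels),
      windows = windows,
      rescale_bounds = rescale_bounds,
      scope = scope
    ),
    class = "dfc_tensor"
  )
}

#' @export
print.dfc_tensor <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<dfc_tensor> %d nodes x %d windows", d[1L], d[3L]))
  if (!is.null(x$rescale_bounds) && is.numeric(x$rescale_bounds) && length(x$rescale_bounds) == 2L) {
    cat(sprintf(", rescaled from [%.4g, %.4g]", x$rescale_bounds[1L], x$rescale_bounds[2L]))
  }
  cat("\n")
  invisible(x)
}

n_nodes <- function(dfc) dim(dfc$weights)[1L]
n_windows_of <- function(dfc) dim(dfc$weights)[3L]

#' @describeIn dfc_tensor Long tibble of per-window edge weights (unordered
#'   pairs `i < j`).
#' @param x A `dfc_tensor`.
#' @param ... Unused.
#' @export
#' @method tidy dfc_tensor
tidy.dfc_tensor <- function(x, ...) {
  n <- n_nodes(x)
  tau <- n_windows_of(x)
  pairs <- upper_pairs(n)
  ut <- upper.tri(diag(n))
  purrr::map_dfr(seq_len(tau), function(t) {
    tibble::tibble(
      window = t,
      node_i = x$node_labels[pairs$i],
      node_j = x$node_labels[pairs$j],
      weight = x$weights[, , t][ut]
    )
  })
}

#' @describeIn dfc_tensor One-row summary (node/window counts, weight range).
#' @export
#' @method glance dfc_tensor
glance.dfc_tensor <- function(x, ...) {
  n <- n_nodes(x)
  mask <- off_diag(n)
  vals <- as.vector(x$weights[array(mask, dim = dim(x$weights))])
  tibble::tibble(
    n_nodes = n,
    n_windows = n_windows_of(x),
    min_weight = min(vals),
    max_weight = max(vals),
    mean_weight = mean(vals)
  )
}

# time-mean weight matrix (N x N)
dfc_time_mean <- function(dfc) {
  apply(dfc$weights, c(1L, 2L), mean)
}

#' Binarize a connectivity tensor at the network-wide mean weight
#'
#' Sets an entry to 1 where its weight strictly exceeds the mean of all
#' off-diagonal weights over all windows of the subject, 0 otherwise (ties at
#' exactly the mean are 0). This is the binarization rule used to feed
#' binary-network filters.
#'
#' @param dfc A [dfc_tensor()].
#' @return An `N x N x tau` integer 0/1 array (symmetric, zero diagonal) with
#'   the cut value attached as attribute `"threshold"`.
#' @export
binarize_tensor <- function(dfc) {
  stopifnot(inherits(dfc, "dfc_tensor"))
  n <- n_nodes(dfc)
  mask <- array(off_diag(n), dim = dim(dfc$weights))
  m <- mean(dfc$weights[mask])
  out <- array(0L, dim = dim(dfc$weights), dimnames = dimnames(dfc$weights))
  out[mask] <- as.integer(dfc$weights[mask] > m)
  attr(out, "threshold") <- m
  out
}
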