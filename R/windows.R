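#' Sliding-window segmentation of a time series
#'
#' Divides `n_time` samples into half-open windows `[s, s + width)` advancing
#' by `width - overlap` samples. Windows are 0-based and trailing samples that
#' do not fill a complete window are dropped.
#'
#' @param n_time Total number of time points `T`.
#' @param width Window length `Delta` in time points.
#' @param overlap Number of time points shared by consecutive windows.
#'
#' @return A `wbn_windows` object: window width, overlap, stride, 0-based
#'   start indices and the window count `tau`.
#'
#' @examples
#' make_windows(100, width = 20, overlap = 5)
#' @export
make_windows <- function(n_time, width, overlap = 0L) {
  n_time <- as.integer(n_time)
  width <- as.integer(width)
  overlap <- as.integer(overlap)
  if (width <= 0L || width > n_time) {
    abort(sprintf("window width must satisfy 0 < width <= T (T=%d, width=%d)", n_time, width))
  }
  if (overlap < 0L || overlap >= width) {
    abort(sprintf("overlap must satisfy 0 <= overlap < width (width=%d, overlap=%d)", width, overlap))
  }
  stride <- width - overlap
  starts <- seq.int(0L, n_time - width, by = stride)
  if (length(starts) < 2L) {
    abort(sprintf(
      "fewer than 2 windows fit: T=%d, width=%d, overlap=%d (stride %d)",
      n_time, width, overlap, stride
    ))
  }
  structure(
    list(
      width = width, overlap = overlap, stride = stride,
      starts = starts, n_windows = length(starts), n_time = n_time
    ),
    class = "wbn_windows"
  )
}

#' @export
print.wbn_windows <- function(x, ...) {
  cat(sprintf(
    "<wbn_windows> tau=%d windows of width %d (overlap %d) over T=%d\n",
    x$n_windows, x$width, x$overlap, x$n_time
  ))
  invisible(x)
}

#' @describeIn make_windows One row per window with 0-based half-open bounds.
#' @param x A `wbn_windows` object.
#' @param ... Unused.
#' @export
#' @method tidy wbn_windows
tidy.wbn_windows <- function(x, ...) {
  tibble::tibble(
    window = seq_len(x$n_windows),
    start = x$starts,
    end = x$starts + x$width
  )
}

# 1-based row indices of window t
window_index <- function(windows, t) {
  (windows$starts[t] + 1L):(windows$starts[t] + windows$width)
}

#' Windowed Pearson correlation tensor
#'
#' Computes, for every sliding window, the Pearson correlation matrix of the
#' node signals, producing the raw (unscaled) dynamic-connectivity tensor.
#' Self-correlations are removed (diagonal set to 0). A node that is constant
#' within a window is a degenerate signal and raises an error naming the node
#' and the window rather than propagating `NA`.
#'
#' @param ts Time series: a data frame or matrix, rows = time points,
#'   columns = nodes.
#' @param windows A [make_windows()] segmentation.
#'
#' @return An `N x N x tau` array of correlations in `[-1, 1]`, symmetric with
#'   zero diagonals, with node labels as dimnames and the window spec attached
#'   as an attribute.
#' @export
windowed_correlation <- function(ts, windows) {
  x <- as_ts_matrix(ts)
  stopifnot(inherits(windows, "wbn_windows"))
  if (windows$width < 3L) abort("window width must be at least 3 for correlation")
  if (windows$n_time != nrow(x)) {
    abort(sprintf(
      "window spec was built for T=%d but the series has %d rows",
      windows$n_time, nrow(x)
    ))
  }
  n <- ncol(x)
  tau <- windows$n_windows
  arr <- array(0, dim = c(n, n, tau), dimnames = list(colnames(x), colnames(x), NULL))
  for (t in seq_len(tau)) {
    seg <- x[window_index(windows, t), , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    if (any(sds == 0)) {
      bad <- colnames(x)[which(sds == 0)[1L]]
      abort(sprintf("node '%s' is constant within window %d: correlation undefined", bad, t))
    }
    cc <- stats::cor(seg)
    diag(cc) <- 0
    arr[, , t] <- cc
  }
  attr(arr, "windows") <- windows
  arr
}

#' Min-max rescaling of a connectivity tensor
#'
#' Affinely maps off-diagonal weights onto `[0, 1]`. By default the minimum
#' and maximum are taken globally over all off-diagonal entries of all windows
#' of the subject, preserving cross-window comparability (the stationary null
#' assumes weights of different windows live on one scale); `per_window`
#' rescales each slice by its own range. Explicit `bounds` override the
#' observed range, e.g. to put surrogate tensors on the original subject's
#' scale.
#'
#' @param raw Raw tensor from [windowed_correlation()] (or any `N x N x tau`
#'   array of symmetric zero-diagonal slices).
#' @param scope `"global"` (default) or `"per_window"`.
#' @param bounds Optional numeric `c(min, max)` overriding the observed range
#'   (only for `scope = "global"`).
#'
#' @return A [dfc_tensor()] with `rescale_bounds` recorded.
#' @export
rescale_minmax <- function(raw, scope = c("global", "per_window"), bounds = NULL) {
  scope <- match.arg(scope)
  if (inherits(raw, "dfc_tensor")) raw_arr <- raw$weights else raw_arr <- raw
  if (!is.array(raw_arr) || length(dim(raw_arr)) != 3L) {
    abort("`raw` must be an N x N x tau array")
  }
  if (any(!is.finite(raw_arr))) abort("`raw` contains non-finite values")
  n <- dim(raw_arr)[1L]
  tau <- dim(raw_arr)[3L]
  mask <- off_diag(n)
  out <- raw_arr
  if (scope == "global") {
    vals <- as.vector(raw_arr[array(mask, dim = dim(raw_arr))])
    rng <- bounds %||% range(vals)
    if (diff(rng) <= 0) abort("degenerate scale: all off-diagonal weights are equal")
    for (t in seq_len(tau)) {
      sl <- (raw_arr[, , t] - rng[1L]) / diff(rng)
      diag(sl) <- 0
      out[, , t] <- sl
    }
    bounds_rec <- rng
  } else {
    if (!is.null(bounds)) abort("explicit `bounds` require scope = \"global\"")
    bounds_rec <- matrix(NA_real_, tau, 2L)
    for (t in seq_len(tau)) {
      sl <- raw_arr[, , t]
      rng <- range(sl[mask])
      if (diff(rng) <= 0) abort(sprintf("degenerate scale in window %d: all weights equal", t))
      sl <- (sl - rng[1L]) / diff(rng)
      diag(sl) <- 0
      out[, , t] <- sl
      bounds_rec[t, ] <- rng
    }
  }
  dfc_tensor(
    out,
    node_labels = dimnames(raw_arr)[[1L]],
    windows = attr(raw, "windows"),
    rescale_bounds = bounds_rec,
    scope = scope
  )
}

#' Average node signals within regions of interest
#'
#' Collapses node columns into region time courses by unweighted averaging,
#' as done when moving from voxel-level to atlas-region analysis.
#'
#' @param ts Time series data frame or matrix (columns = nodes).
#' @param labels Character vector, one region id per node column.
#'
#' @return A tibble of region time courses (one column per distinct region,
#'   in order of first appearance).
#' @export
aggregate_rois <- function(ts, labels) {
  x <- as_ts_matrix(ts)
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) {
    abort(sprintf(
      "`labels` must have one entry per node: got %d labels for %d nodes",
      length(labels), ncol(x)
    ))
  }
  if (any(!nzchar(labels))) abort("region labels must be non-empty")
  regions <- unique(labels)
  out <- vapply(
    regions,
    function(r) rowMeans(x[, labels == r, drop = FALSE]),
    numeric(nrow(x))
  )
  tibble::as_tibble(out)
}

#' Build a dynamic-connectivity tensor from a time series
#'
#' Convenience wrapper chaining [make_windows()], [windowed_correlation()]
#' and [rescale_minmax()].
#'
#' @inheritParams windowed_correlation
#' @inheritParams make_windows
#' @inheritParams rescale_minmax
#' @return A [dfc_tensor()].
#' @export
build_dfc <- function(ts, width, overlap = 0L, scope = "global", bounds = NULL) {
  x <- as_ts_matrix(ts)
  w <- make_windows(nrow(x), width, overlap)
  rescale_minmax(windowed_correlation(x, w), scope = scope, bounds = bounds)
}
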