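# internal helpers shared across modules

# coerce a data frame / tibble / matrix of node signals to a T x N numeric
# matrix with unique column labels; enforces the time-series invariants
as_ts_matrix <- function(ts, arg = "ts") {
  if (is.data.frame(ts)) {
    non_num <- !vapply(ts, is.numeric, logical(1))
    if (any(non_num)) {
      abort(sprintf(
        "all columns of `%s` must be numeric node signals; offending: %s",
        arg, paste(names(ts)[non_num], collapse = ", ")
      ))
    }
    x <- as.matrix(ts)
  } else if (is.matrix(ts) && is.numeric(ts)) {
    x <- ts
  } else {
    abort(sprintf("`%s` must be a numeric matrix or all-numeric data frame", arg))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("node_", seq_len(ncol(x)))
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values", arg))
  }
  if (nrow(x) < 2L) abort(sprintf("`%s` needs at least 2 time points", arg))
  if (ncol(x) < 3L) abort(sprintf("`%s` needs at least 3 nodes", arg))
  if (anyDuplicated(colnames(x))) abort(sprintf("`%s` node labels must be unique", arg))
  x
}

# logical mask of off-diagonal cells
off_diag <- function(n) {
  m <- matrix(TRUE, n, n)
  diag(m) <- FALSE
  m
}

# tibble of unordered node pairs i < j (integer indices)
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1L], j = idx[, 2L])
}

# extract the upper-triangle vector (i < j) of a square matrix
utri <- function(m) m[upper.tri(m)]

# rebuild a symmetric matrix (zero diagonal) from its upper-triangle vector
sym_from_utri <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

check_square <- function(m, n = NULL, arg = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort(sprintf("`%s` must be square", arg))
  if (!is.null(n) && nrow(m) != n) {
    abort(sprintf("`%s` must be %d x %d, got %d x %d", arg, n, n, nrow(m), ncol(m)))
  }
  invisible(m)
}

# derive a stage seed from a root seed, staying inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + offset) %% 2147483647)
}
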