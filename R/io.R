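#' Read a delimited time-series matrix
#'
#' Reads a CSV (`.csv`) or TSV (anything else) file with a header row of node
#' labels into a tibble of node signals.
#'
#' @param path File path.
#' @return A tibble (rows = time points, columns = nodes).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_ts_matrix(out) # validate
  out
}

#' @rdname read_timeseries
#' @param ts Time series (data frame or matrix).
#' @export
write_timeseries <- function(ts, path) {
  x <- as_ts_matrix(ts)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tibble::as_tibble(x), path, delim = delim)
  invisible(path)
}

# labeled adjacency matrix <-> TSV with labels as header row and first column
write_adjacency <- function(m, labels, path) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  names(df) <- labels
  df <- dplyr::bind_cols(tibble::tibble(node = labels), df)
  readr::write_tsv(df, path)
  invisible(path)
}

read_adjacency <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  labels <- df[[1L]]
  m <- as.matrix(df[, -1L])
  rownames(m) <- labels
  if (!identical(colnames(m), as.character(labels))) {
    abort(sprintf("adjacency file %s: header and label column disagree", path))
  }
  m
}

#' Write / read a dynamic-connectivity tensor
#'
#' The tensor is stored as one TSV adjacency matrix per window
#' (`win_0000.tsv`, `win_0001.tsv`, ...) plus a JSON sidecar (`dfc.json`)
#' holding node labels, window boundaries, rescale bounds and scope.
#'
#' @param dfc A [dfc_tensor()].
#' @param dir Directory (created if missing).
#' @return `write_dfc` returns the directory invisibly; `read_dfc` a
#'   [dfc_tensor()].
#' @export
write_dfc <- function(dfc, dir) {
  stopifnot(inherits(dfc, "dfc_tensor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tau <- n_windows_of(dfc)
  for (t in seq_len(tau)) {
    write_adjacency(dfc$weights[, , t], dfc$node_labels,
                    file.path(dir, sprintf("win_%04d.tsv", t - 1L)))
  }
  side <- list(
    node_labels = dfc$node_labels,
    n_windows = tau,
    scope = dfc$scope,
    rescale_bounds = dfc$rescale_bounds
  )
  if (!is.null(dfc$windows)) {
    side$windows <- list(
      width = dfc$windows$width, overlap = dfc$windows$overlap,
      starts = dfc$windows$starts, n_time = dfc$windows$n_time
    )
  }
  jsonlite::write_json(side, file.path(dir, "dfc.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_dfc
#' @export
read_dfc <- function(dir) {
  side_path <- file.path(dir, "dfc.json")
  if (!file.exists(side_path)) abort(sprintf("missing sidecar: %s", side_path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  tau <- side$n_windows
  labels <- side$node_labels
  n <- length(labels)
  arr <- array(0, dim = c(n, n, tau))
  for (t in seq_len(tau)) {
    arr[, , t] <- read_adjacency(file.path(dir, sprintf("win_%04d.tsv", t - 1L)))
  }
  windows <- NULL
  if (!is.null(side$windows)) {
    windows <- make_windows(side$windows$n_time, side$windows$width, side$windows$overlap)
  }
  dfc_tensor(arr, node_labels = labels, windows = windows,
             rescale_bounds = side$rescale_bounds, scope = side$scope)
}

#' Write / read fitted latent parameters
#'
#' Parameters go to `<prefix>.tsv` (node, a, b); solver diagnostics to
#' `<prefix>.json`.
#'
#' @param params A [latent_params()].
#' @param prefix Path prefix (without extension).
#' @return `write_latent` returns the prefix invisibly; `read_latent` a
#'   [latent_params()].
#' @export
write_latent <- function(params, prefix) {
  stopifnot(inherits(params, "latent_params"))
  readr::write_tsv(tidy(params), paste0(prefix, ".tsv"))
  jsonlite::write_json(
    list(
      residual_norm = params$residual_norm,
      converged = params$converged,
      iterations = params$iterations,
      solver = params$solver_name
    ),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_latent
#' @export
read_latent <- function(prefix) {
  tab <- readr::read_tsv(paste0(prefix, ".tsv"), show_col_types = FALSE,
                         progress = FALSE)
  diag_path <- paste0(prefix, ".json")
  dg <- if (file.exists(diag_path)) jsonlite::read_json(diag_path, simplifyVector = TRUE) else list()
  suppressWarnings(latent_params(
    tab$a, tab$b, node_labels = tab$node,
    residual_norm = dg$residual_norm %||% NA_real_,
    converged = dg$converged %||% NA,
    iterations = dg$iterations %||% NA_integer_,
    solver_name = dg$solver %||% "unknown"
  ))
}

#' Export a backbone result
#'
#' Writes the binary backbone, exceedance counts and (if present) weighted
#' backbone as labeled TSV adjacency matrices, plus `summary.json` with the
#' configuration, admitted-link count and per-node share of significant ties.
#'
#' @param result A `backbone_result` from [extract_backbone()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_backbone <- function(result, dir) {
  stopifnot(inherits(result, "backbone_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_adjacency(result$binary, result$node_labels, file.path(dir, "binary.tsv"))
  write_adjacency(result$counts, result$node_labels, file.path(dir, "counts.tsv"))
  if (!is.null(result$weighted)) {
    write_adjacency(result$weighted, result$node_labels, file.path(dir, "weighted.tsv"))
  }
  share <- share_significant_ties(result)
  jsonlite::write_json(
    list(
      alpha = result$config$alpha,
      alpha_effective = result$alpha_effective,
      count_fraction = result$config$count_fraction,
      correction = result$config$correction,
      tau = result$tau,
      n_admitted = sum(utri(result$binary)),
      share_significant_ties = stats::setNames(as.list(share$share), share$node)
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
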