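#' Run configuration for the backbone pipeline
#'
#' Bundles every knob of a full run. Defaults mirror the standard analysis
#' setup: `alpha = 0.2` (80th-percentile test), admission in strictly more
#' than half the windows, no multiple-testing correction.
#'
#' @param input Path to a delimited time-series file, or an in-memory data
#'   frame / matrix of node signals.
#' @param width,overlap Sliding-window width and overlap (time points).
#' @param alpha Significance level in (0, 1).
#' @param count_fraction Aggregation fraction in (0, 1).
#' @param correction `"none"`, `"bonferroni_count"` or
#'   `"bonferroni_weight_sum"`.
#' @param scope Min-max rescaling scope, `"global"` or `"per_window"`.
#' @param null_method `"wbn"` (latent model), `"arr"` or `"pr"` (surrogate
#'   baselines).
#' @param n_surrogates Surrogate ensemble size (ARR/PR only).
#' @param ar_order VAR order (ARR only).
#' @param seed Root integer seed.
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @param roi_labels Optional per-node region labels; when given, node
#'   signals are averaged within regions before windowing.
#'
#' @return A validated `wbn_run_config`.
#' @export
wbn_config <- function(input, width, overlap = 0L, alpha = 0.2,
                       count_fraction = 0.5, correction = "none",
                       scope = "global", null_method = "wbn",
                       n_surrogates = 50L, ar_order = 1L, seed = 1L,
                       out_dir = NULL, roi_labels = NULL) {
  validate_config(list(
    input = input, width = width, overlap = overlap, alpha = alpha,
    count_fraction = count_fraction, correction = correction, scope = scope,
    null_method = null_method, n_surrogates = n_surrogates,
    ar_order = ar_order, seed = seed, out_dir = out_dir,
    roi_labels = roi_labels
  ))
}

#' Validate a raw pipeline configuration
#'
#' Checks every constraint and reports all violations at once (not just the
#' first), fills defaults, and returns the validated configuration.
#'
#' @param raw A named list of configuration values (see [wbn_config()]), or a
#'   path to a JSON file of them.
#' @return A `wbn_run_config`.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- jsonlite::read_json(raw, simplifyVector = TRUE)
  }
  if (!is.list(raw)) abort("configuration must be a named list or a JSON file path")
  defaults <- list(
    overlap = 0L, alpha = 0.2, count_fraction = 0.5, correction = "none",
    scope = "global", null_method = "wbn", n_surrogates = 50L,
    ar_order = 1L, seed = 1L, out_dir = NULL, roi_labels = NULL
  )
  for (nm in names(defaults)) {
    if (is.null(raw[[nm]])) raw[nm] <- defaults[nm]
  }
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (is.null(raw$input)) note("`input` is required (path or data frame)")
  if (is.null(raw$width)) {
    note("`width` is required")
  } else if (!is.numeric(raw$width) || raw$width < 3) {
    note("`width` must be a number >= 3")
  }
  if (!is.numeric(raw$overlap) || raw$overlap < 0) {
    note("`overlap` must be a nonnegative number")
  } else if (is.numeric(raw$width) && raw$overlap >= raw$width) {
    note(sprintf("`overlap` (%g) must be smaller than `width` (%g)", raw$overlap, raw$width))
  }
  if (!is.numeric(raw$alpha) || raw$alpha <= 0 || raw$alpha >= 1) {
    note(sprintf("`alpha` must be in (0, 1), got %s", format(raw$alpha)))
  }
  if (!is.numeric(raw$count_fraction) || raw$count_fraction <= 0 || raw$count_fraction >= 1) {
    note("`count_fraction` must be in (0, 1)")
  }
  if (!raw$correction %in% c("none", "bonferroni_count", "bonferroni_weight_sum")) {
    note(sprintf("unknown `correction`: %s", raw$correction))
  }
  if (!raw$scope %in% c("global", "per_window")) {
    note(sprintf("unknown `scope`: %s", raw$scope))
  }
  if (!raw$null_method %in% c("wbn", "arr", "pr")) {
    note(sprintf("unknown `null_method`: %s (use wbn, arr or pr)", raw$null_method))
  }
  if (!is.numeric(raw$n_surrogates) || raw$n_surrogates < 1) {
    note("`n_surrogates` must be a positive integer")
  }
  if (!is.numeric(raw$seed)) note("`seed` must be an integer")

  if (length(problems) > 0L) {
    abort(paste0(
      "invalid configuration:\n",
      paste0("  - ", problems, collapse = "\n")
    ))
  }
  raw$width <- as.integer(raw$width)
  raw$overlap <- as.integer(raw$overlap)
  raw$seed <- as.integer(raw$seed)
  structure(raw, class = "wbn_run_config")
}

#' Run the full backbone pipeline
#'
#' Executes read -> (optional ROI averaging) -> window -> correlate ->
#' rescale -> estimate -> filter -> aggregate, writes artifacts (backbone,
#' counts, latent parameters, manifest) when `out_dir` is set, and returns
#' the fitted objects.
#'
#' @param config A [wbn_config()] (or raw list / JSON path accepted by
#'   [validate_config()]).
#' @return Invisibly, a list with `dfc`, `params` (NULL for surrogate
#'   baselines), `backbone`, and `manifest`.
#' @export
run_wbn <- function(config) {
  if (!inherits(config, "wbn_run_config")) config <- validate_config(config)
  ts <- config$input
  input_desc <- "in-memory"
  if (is.character(ts)) {
    input_desc <- ts
    ts <- read_timeseries(ts)
  }
  x <- as_ts_matrix(ts)
  if (!is.null(config$roi_labels)) {
    inform(sprintf("averaging %d nodes into regions", ncol(x)))
    x <- as_ts_matrix(aggregate_rois(x, config$roi_labels))
  }
  windows <- make_windows(nrow(x), config$width, config$overlap)
  inform(sprintf("segmented T=%d into tau=%d windows of width %d",
                 nrow(x), windows$n_windows, config$width))
  cfg <- significance_config(config$alpha, config$count_fraction, config$correction)

  if (config$null_method == "wbn") {
    dfc <- rescale_minmax(windowed_correlation(x, windows), scope = config$scope)
    params <- solve_latent(dfc)
    inform(sprintf("latent fit: residual max-norm %.3g (%s)",
                   params$residual_norm, if (params$converged) "converged" else "NOT converged"))
    backbone <- extract_backbone(dfc, params = params, config = cfg)
  } else {
    if (config$scope != "global") abort("surrogate baselines require scope = \"global\"")
    dfc <- rescale_minmax(windowed_correlation(x, windows), scope = "global")
    params <- NULL
    backbone <- surrogate_backbone(
      x, windows, method = config$null_method,
      n_surrogates = config$n_surrogates, alpha = config$alpha,
      seed = derive_seed(config$seed, 5L), order = config$ar_order,
      count_fraction = config$count_fraction, dfc = dfc
    )
  }
  inform(sprintf("%d of %d pairs admitted to the backbone",
                 sum(utri(backbone$binary)), ncol(x) * (ncol(x) - 1) / 2))

  manifest <- list(
    package_version = as.character(utils::packageVersion("wbnet")),
    input = input_desc,
    input_hash = rlang::hash(x),
    n_time = nrow(x), n_nodes = ncol(x),
    width = config$width, overlap = config$overlap,
    tau = windows$n_windows,
    alpha = config$alpha, count_fraction = config$count_fraction,
    correction = config$correction, scope = config$scope,
    null_method = config$null_method, seed = config$seed,
    rescale_bounds = dfc$rescale_bounds,
    residual_norm = if (is.null(params)) NULL else params$residual_norm,
    converged = if (is.null(params)) NULL else params$converged,
    n_admitted = sum(utri(backbone$binary))
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_backbone(backbone, config$out_dir)
    if (!is.null(params)) write_latent(params, file.path(config$out_dir, "latent"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(dfc = dfc, params = params, backbone = backbone, manifest = manifest))
}
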