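# ggplot2 displays for the main result types

heatmap_df <- function(m, labels) {
  tibble::tibble(
    node_i = factor(rep(labels, times = ncol(m)), levels = labels),
    node_j = factor(rep(labels, each = nrow(m)), levels = labels),
    value = as.vector(m)
  )
}

#' @describeIn dfc_tensor Heatmap of time-mean connectivity weights.
#' @param object A `dfc_tensor`.
#' @export
#' @method autoplot dfc_tensor
autoplot.dfc_tensor <- function(object, ...) {
  df <- heatmap_df(dfc_time_mean(object), object$node_labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$node_j, .data$node_i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean weight") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Time-mean dynamic connectivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn extract_backbone Heatmap of the exceedance counts or binary
#'   backbone.
#' @param object A `backbone_result`.
#' @param type `"counts"` (default) or `"binary"`.
#' @export
#' @method autoplot backbone_result
autoplot.backbone_result <- function(object, type = c("counts", "binary"), ...) {
  type <- match.arg(type)
  m <- if (type == "counts") object$counts else object$binary
  df <- heatmap_df(m, object$node_labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$node_j, .data$node_i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Backbone %s (alpha=%g, tau=%d)", type, object$config$alpha, object$tau)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (type == "counts") {
    p + ggplot2::scale_fill_viridis_c(name = "exceedances")
  } else {
    p + ggplot2::scale_fill_gradient(name = "admitted", low = "grey15", high = "white")
  }
}

#' @describeIn group_consensus Heatmap of the display-filtered consensus.
#' @param object A `wbn_consensus`.
#' @export
#' @method autoplot wbn_consensus
autoplot.wbn_consensus <- function(object, ...) {
  labels <- rownames(object$mean) %||% paste0("node_", seq_len(nrow(object$mean)))
  df <- heatmap_df(object$display, labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$node_j, .data$node_i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "fraction of\nsubjects", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Group consensus backbone (n=%d, floor=%g)",
                      object$n_subjects, object$display_floor)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a normality sweep
#'
#' Mean per-pair normality p value against window size.
#'
#' @param report A [ks_normality_sweep()] result.
#' @return A ggplot.
#' @export
plot_normality_sweep <- function(report) {
  stopifnot(inherits(report, "normality_report"))
  ggplot2::ggplot(report, ggplot2::aes(.data$delta, .data$mean_pvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "window size (time points)", y = "mean KS p value",
      title = "Normality of temporal tie distributions"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an injected-link detection benchmark
#'
#' AUC per detection route.
#'
#' @param report A [detection_benchmark()] result.
#' @return A ggplot.
#' @export
plot_detection_benchmark <- function(report) {
  stopifnot(inherits(report, "detection_report"))
  ggplot2::ggplot(report, ggplot2::aes(.data$method, .data$auc)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "AUC",
      title = "Detection of injected random link weights"
    ) +
    ggplot2::theme_minimal()
}
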