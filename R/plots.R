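#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a detection trace
#'
#' Detection runs as shaded strips over time, optionally with annotated SD
#' onsets as dashed vertical lines.
#'
#' @param object An `sd_detection`.
#' @param onsets_s Optional annotated onsets (s).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sd_detection <- function(object, onsets_s = NULL, ...) {
  p <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$time_s / 60,
                                    y = .data$detected)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = expression(T[out]),
                  title = "SD detection trace") +
    ggplot2::scale_y_continuous(breaks = c(0, 1), limits = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(onsets_s) && length(onsets_s)) {
    p <- p + ggplot2::geom_vline(xintercept = onsets_s / 60,
                                 linetype = "dashed", colour = "red3")
  }
  p
}

#' Plot averaged cross-validation ROC curves
#'
#' Validation (and train) threshold-averaged ROC points with the optimal
#' operating point marked.
#'
#' @param object An `sd_cv` from [l2o_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sd_cv <- function(object, ...) {
  roc <- dplyr::mutate(object$roc, set = "validation")
  troc <- dplyr::mutate(object$train_roc, set = "train", eps_cv = NA_real_)
  both <- dplyr::bind_rows(roc, troc)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                     colour = .data$set)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$optimal,
                        ggplot2::aes(x = .data$fpr, y = .data$tpr),
                        inherit.aes = FALSE, shape = 8, size = 3) +
    ggplot2::labs(x = "FPR", y = "TPR",
                  title = "Leave-2-out cross-validation ROC (threshold-averaged)") +
    ggplot2::theme_minimal()
}

#' Plot the SD-frequency square-root regression
#'
#' Scatter of detection duration against annotated SD count with the fitted
#' `a sqrt(x) + b` curve.
#'
#' @param object A `sqrt_fit` from [fit_sqrt()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sqrt_fit <- function(object, ...) {
  xs <- seq(0, max(object$data$x), length.out = 200)
  curve <- tibble::tibble(x = xs, y = object$a * sqrt(xs) + object$b)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_line(data = curve, colour = "red3") +
    ggplot2::labs(x = "annotated SDs per window",
                  y = "total detection duration (min)",
                  title = sprintf("y = %.2f sqrt(x) + %.2f  (R2 = %.2f, RMSE = %.1f SDs)",
                                  object$a, object$b, object$r_squared,
                                  object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a scalp topographic frame
#'
#' Heat map of one frame of an `sd_topo` stack with electrode positions
#' overlaid; handy when debugging the projection/thresholding stages.
#'
#' @param topo An `sd_topo`.
#' @param frame Frame index.
#' @return A ggplot.
#' @export
plot_topo_frame <- function(topo, frame = 1) {
  img <- topo$frames[, , frame]
  df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(img)
  el <- tibble::tibble(row = topo$electrode_px[, 1],
                       col = topo$electrode_px[, 2],
                       label = topo$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_text(data = el,
                       ggplot2::aes(x = .data$col, y = .data$row,
                                    label = .data$label),
                       inherit.aes = FALSE, colour = "white", size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "azimuth (px)", y = "polar (px)",
                  title = sprintf("%s frame %d (t = %.0f s)", topo$stage,
                                  frame, topo$times[frame])) +
    ggplot2::theme_minimal()
}
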