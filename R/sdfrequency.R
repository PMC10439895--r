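#' Prune and stitch detection runs at the 30-hour scale
#'
#' For SD-burden estimation the fine-grained detection trace is cleaned at a
#' much larger temporal scale than the tracker's own stitching: detection
#' runs shorter than `min_run_min` minutes whose edge-to-edge distance to
#' the nearest other run exceeds `isolation_h` hours are removed as isolated
#' false alarms, and the remaining runs are merged whenever they lie within
#' `stitch_h` hours of each other. The total duration of the merged spans is
#' returned in minutes.
#'
#' @param runs Tibble with `start_s`, `end_s` (or an `sd_detection`).
#' @param min_run_min Minimum isolated-run length kept (default 20 min).
#' @param isolation_h Isolation distance (default 4 h).
#' @param stitch_h Stitching window (default 4 h).
#' @return Total detection duration in minutes (0 for an empty trace).
#' @export
prune_stitch <- function(runs, min_run_min = 20, isolation_h = 4,
                         stitch_h = 4) {
  if (inherits(runs, "sd_detection")) runs <- runs$runs
  if (!nrow(runs)) return(0)
  runs <- runs[order(runs$start_s), , drop = FALSE]
  n <- nrow(runs)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    len_min <- (runs$end_s[i] - runs$start_s[i]) / 60
    if (len_min >= min_run_min) next
    gaps <- c(
      if (i > 1) runs$start_s[i] - runs$end_s[seq_len(i - 1)],
      if (i < n) runs$start_s[(i + 1):n] - runs$end_s[i])
    if (!length(gaps) || min(abs(gaps)) / 3600 > isolation_h) {
      keep[i] <- FALSE
    }
  }
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(0)
  merged_start <- runs$start_s[1]
  merged_end <- runs$end_s[1]
  total_s <- 0
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start_s[i] - merged_end <= stitch_h * 3600) {
        merged_end <- max(merged_end, runs$end_s[i])
      } else {
        total_s <- total_s + (merged_end - merged_start)
        merged_start <- runs$start_s[i]
        merged_end <- runs$end_s[i]
      }
    }
  }
  total_s <- total_s + (merged_end - merged_start)
  total_s / 60
}

#' Build 30-hour SD-frequency windows
#'
#' Slides 30-h windows in 1-h steps over a detection trace, recording per
#' window the annotated SD count `x`, the pruned/stitched total detection
#' duration `y` (minutes) and a quality flag requiring at least
#' `min_good_h` hours of unmasked signal on at least `min_electrodes`
#' ipsilateral electrodes.
#'
#' @param detection An `sd_detection`.
#' @param onsets_s Annotated SD onsets (s).
#' @param quality Optional tibble (`time_s`, `n_good`).
#' @param window_h,step_h Window length and step (hours).
#' @param min_good_h,min_electrodes Quality gate.
#' @param ... Passed to [prune_stitch()].
#' @return Tibble (`start_s`, `x`, `y`, `quality_ok`).
#' @export
frequency_windows <- function(detection, onsets_s, quality = NULL,
                              window_h = 30, step_h = 1,
                              min_good_h = 20, min_electrodes = 5, ...) {
  trace <- detection$trace
  t_end <- max(trace$time_s) + detection$frame_dt
  w_s <- window_h * 3600
  starts <- seq(0, max(0, t_end - w_s), by = step_h * 3600)
  runs <- detection$runs
  rows <- lapply(starts, function(s) {
    e <- s + w_s
    in_w <- runs[runs$end_s > s & runs$start_s < e, , drop = FALSE]
    in_w$start_s <- pmax(in_w$start_s, s)
    in_w$end_s <- pmin(in_w$end_s, e)
    y <- prune_stitch(in_w, ...)
    ok <- TRUE
    if (!is.null(quality)) {
      q <- quality[quality$time_s >= s & quality$time_s < e, ]
      dt <- if (nrow(quality) > 1) diff(quality$time_s[1:2]) else 1
      ok <- sum(q$n_good >= min_electrodes) * dt / 3600 >= min_good_h
    }
    tibble::tibble(start_s = s, x = sum(onsets_s >= s & onsets_s < e),
                   y = y, quality_ok = ok)
  })
  dplyr::bind_rows(rows)
}

#' Square-root regression of detection duration on SD count
#'
#' Fits `y = a sqrt(x) + b` by least squares, where `x` is the annotated SD
#' count and `y` the total detection duration (minutes) in a 30-h window.
#' The square-root form captures the sublinear growth of detection duration
#' when clustered SDs are under-detected. The inverse estimator
#' `xhat = ((y - b) / a)^2` (negative numerators clipped to 0) converts a
#' duration back into an SD count; RMSE is reported on those inverted
#' counts, R-squared on the `y`-space fit.
#'
#' @param data Data frame with the predictor and response.
#' @param x,y Column names (strings) of the SD count and duration.
#' @return A `sqrt_fit` object (fields `a`, `b`, `r_squared`, `rmse`,
#'   `fitted`, `xhat`, and the underlying `lm`). Supports `tidy()`,
#'   `glance()`, `predict()` and `autoplot()`.
#' @examples
#' d <- data.frame(n_sd = 0:10, minutes = 3 * sqrt(0:10) + 5)
#' fit <- fit_sqrt(d, "n_sd", "minutes")
#' glance(fit)
#' @export
fit_sqrt <- function(data, x = "x", y = "y") {
  xs <- data[[x]]
  ys <- data[[y]]
  stopifnot(length(xs) >= 3, all(xs >= 0))
  if (length(unique(xs)) < 2) {
    stop("all SD counts identical: singular design")
  }
  df <- data.frame(.sqrt_x = sqrt(xs), .y = ys)
  fit <- stats::lm(.y ~ .sqrt_x, data = df)
  a <- unname(stats::coef(fit)[".sqrt_x"])
  b <- unname(stats::coef(fit)["(Intercept)"])
  xhat <- sqrt_inverse(ys, a, b)
  structure(
    list(a = a, b = b,
         r_squared = summary(fit)$r.squared,
         rmse = sqrt(mean((xs - xhat)^2)),
         fitted = stats::fitted(fit), xhat = xhat,
         lm = fit, data = tibble::tibble(x = xs, y = ys)),
    class = "sqrt_fit"
  )
}

#' @rdname fit_sqrt
#' @param a,b Fitted coefficients.
#' @export
sqrt_inverse <- function(y, a, b) pmax(0, (y - b) / a)^2

#' @export
print.sqrt_fit <- function(x, ...) {
  cat(sprintf("<sqrt_fit> y = %.3f sqrt(x) + %.3f; R2 = %.3f, RMSE = %.2f SDs (n = %d)\n",
              x$a, x$b, x$r_squared, x$rmse, nrow(x$data)))
  invisible(x)
}

#' @export
tidy.sqrt_fit <- function(x, ...) {
  tibble::tibble(term = c("sqrt_x", "intercept"),
                 estimate = c(x$a, x$b),
                 std.error = summary(x$lm)$coefficients[c(".sqrt_x", "(Intercept)"), "Std. Error"])
}

#' @export
glance.sqrt_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r_squared = x$r_squared,
                 rmse = x$rmse, n = nrow(x$data))
}

#' @export
predict.sqrt_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  object$a * sqrt(x) + object$b
}
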