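#' Split a recording into normalized epochs
#'
#' Cuts the preprocessed recording into overlapping 240-min epochs advancing
#' by 180 min and normalizes each channel by the standard deviation of its
#' valid samples within the epoch. Normalization equalizes the heterogeneous
#' baseline power across electrodes (breach-rhythm asymmetry over the skull
#' defect) and over time, so that depressions on low-power electrodes survive
#' the later interpolation/thresholding stage. A trailing segment shorter
#' than a full epoch is returned as an epoch flagged `tail = TRUE`; channels
#' with no amplitude variability (zero standard deviation) are fully masked
#' with a warning.
#'
#' @param rec A preprocessed `sd_recording`.
#' @param epoch_s Epoch length in seconds (default 14400 = 240 min).
#' @param step_s Epoch step in seconds (default 10800 = 180 min).
#' @return List of `sd_epoch` objects (fields `data`, `mask`, `fs`, `labels`,
#'   `start_s`, `tail`, `norm_sd`).
#' @export
epoch_and_normalize <- function(rec, epoch_s = 14400, step_s = 10800) {
  stopifnot(inherits(rec, "sd_recording"))
  n <- ncol(rec$data)
  dur <- n / rec$fs
  starts <- seq(0, by = step_s, length.out = max(1, floor((dur - epoch_s) / step_s) + 1))
  starts <- starts[starts + epoch_s <= dur + 1e-9]
  if (!length(starts)) starts <- numeric(0)
  tail_start <- if (length(starts)) max(starts) + step_s else 0
  out <- lapply(starts, function(s) {
    make_epoch(rec, s, epoch_s, tail = FALSE)
  })
  if (tail_start < dur - 1e-9) {
    out <- c(out, list(make_epoch(rec, tail_start, dur - tail_start,
                                  tail = TRUE)))
  }
  out
}

make_epoch <- function(rec, start_s, length_s, tail) {
  i0 <- round(start_s * rec$fs) + 1L
  i1 <- min(ncol(rec$data), round((start_s + length_s) * rec$fs))
  data <- rec$data[, i0:i1, drop = FALSE]
  mask <- rec$mask[, i0:i1, drop = FALSE]
  norm_sd <- rep(NA_real_, nrow(data))
  for (ch in seq_len(nrow(data))) {
    v <- mask[ch, ]
    if (sum(v) < 2) { mask[ch, ] <- FALSE; next }
    s <- stats::sd(data[ch, v])
    if (!is.finite(s) || s == 0) {
      warning("channel ", rec$labels[ch],
              ": zero variance in epoch; channel masked")
      mask[ch, ] <- FALSE
      next
    }
    data[ch, ] <- data[ch, ] / s
    norm_sd[ch] <- s
  }
  data[!mask] <- 0
  structure(
    list(data = data, mask = mask, fs = rec$fs, labels = rec$labels,
         start_s = start_s, tail = tail, norm_sd = norm_sd,
         dhc_side = rec$dhc_side, band = rec$band),
    class = "sd_epoch"
  )
}

#' @export
print.sd_epoch <- function(x, ...) {
  cat(sprintf("<sd_epoch> start %.0f s, %.1f min, %d ch%s\n", x$start_s,
              ncol(x$data) / x$fs / 60, nrow(x$data),
              if (x$tail) " (tail)" else ""))
  invisible(x)
}

#' Mask short isolated valid intervals
#'
#' Valid runs shorter than `min_len_s` whose edge-to-edge gap to the nearest
#' other valid run of the same channel exceeds `isolation_s` are masked.
#' Such islands are too short to carry the slow depression of a spreading
#' depolarization and would otherwise seed false edges.
#'
#' @param epoch An `sd_epoch`.
#' @param min_len_s Minimum run length kept unconditionally (default 1200 s
#'   = 20 min).
#' @param isolation_s Isolation gap (default 60 s).
#' @return The epoch with isolated islands masked.
#' @export
mask_isolated_intervals <- function(epoch, min_len_s = 1200,
                                    isolation_s = 60) {
  stopifnot(inherits(epoch, "sd_epoch"))
  for (ch in seq_len(nrow(epoch$mask))) {
    r <- rle(epoch$mask[ch, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    vi <- which(r$values)
    if (length(vi) < 1) next
    for (j in seq_along(vi)) {
      i <- vi[j]
      len_s <- r$lengths[i] / epoch$fs
      if (len_s >= min_len_s) next
      gap_prev <- if (j > 1) (starts[i] - ends[vi[j - 1]] - 1L) / epoch$fs else Inf
      gap_next <- if (j < length(vi)) (starts[vi[j + 1]] - ends[i] - 1L) / epoch$fs else Inf
      if (min(gap_prev, gap_next) > isolation_s) {
        epoch$mask[ch, starts[i]:ends[i]] <- FALSE
      }
    }
  }
  epoch$data[!epoch$mask] <- 0
  epoch
}

# frame-series container shared by envelopes and depression signals:
# values ch x frames, valid ch x frames, frame times relative to recording
new_series <- function(values, valid, times, frame_dt, labels, kind) {
  structure(
    list(values = values, valid = valid, times = times, frame_dt = frame_dt,
         labels = labels, kind = kind),
    class = "sd_series"
  )
}

#' @export
print.sd_series <- function(x, ...) {
  cat(sprintf("<sd_series:%s> %d ch x %d frames, dt = %g s\n", x$kind,
              nrow(x$values), ncol(x$values), x$frame_dt))
  invisible(x)
}

# windowed mean of f(x) over valid samples via cumulative sums;
# returns list(value, n_valid) per frame centre
masked_window_mean <- function(x, valid, fs, centers_i, half_n) {
  cx <- cumsum(ifelse(valid, x, 0))
  cv <- cumsum(as.numeric(valid))
  lo <- pmax(1L, centers_i - half_n)
  hi <- pmin(length(x), centers_i + half_n)
  # guard the index before subsetting: cx[0] would drop the element and
  # misalign every following window
  sx <- cx[hi] - cum_at(cx, lo - 1L)
  sv <- cv[hi] - cum_at(cv, lo - 1L)
  list(mean = ifelse(sv > 0, sx / sv, NA_real_), n = sv)
}

#' Extract RMS power envelopes
#'
#' Amplitudes of the normalized epoch are squared, and the RMS of the
#' resulting power signal is taken over a centred sliding window of
#' `win_s` seconds, evaluated every `frame_dt_s` seconds and restricted to
#' valid samples. Frames whose window extends outside the epoch or contains
#' no valid sample are marked invalid (no zero padding, so mask boundaries
#' cannot fake depression edges).
#'
#' @param epoch A normalized `sd_epoch`.
#' @param win_s RMS window (default 300 s = 5 min).
#' @param frame_dt_s Envelope sampling interval (default 10 s).
#' @return An `sd_series` of kind `"envelope"`.
#' @export
rms_envelope <- function(epoch, win_s = 300, frame_dt_s = 10) {
  stopifnot(inherits(epoch, "sd_epoch"))
  fs <- epoch$fs
  n <- ncol(epoch$data)
  half_n <- round(win_s / 2 * fs)
  centers_i <- seq(half_n + 1L, n - half_n, by = round(frame_dt_s * fs))
  if (!length(centers_i)) stop("epoch shorter than the envelope window")
  vals <- matrix(NA_real_, nrow(epoch$data), length(centers_i))
  valid <- matrix(FALSE, nrow(epoch$data), length(centers_i))
  for (ch in seq_len(nrow(epoch$data))) {
    p2 <- epoch$data[ch, ]^4           # (squared amplitude)^2 for the RMS
    w <- masked_window_mean(p2, epoch$mask[ch, ], fs, centers_i, half_n)
    ok <- w$n > 0
    vals[ch, ok] <- sqrt(w$mean[ok])
    valid[ch, ] <- ok
  }
  vals[!valid] <- 0
  new_series(vals, valid, epoch$start_s + (centers_i - 1) / fs,
             frame_dt_s, epoch$labels, "envelope")
}

#' Frame-averaged signal series (near-DC path)
#'
#' For the near-DC band the depression kernel is applied directly to the
#' normalized signal rather than to a power envelope; this helper averages
#' the signal into frames on the same grid the envelope extractor uses.
#'
#' @inheritParams rms_envelope
#' @export
signal_series <- function(epoch, frame_dt_s = 10) {
  stopifnot(inherits(epoch, "sd_epoch"))
  fs <- epoch$fs
  n <- ncol(epoch$data)
  half_n <- max(1L, round(frame_dt_s / 2 * fs))
  centers_i <- seq(half_n + 1L, n - half_n, by = round(frame_dt_s * fs))
  vals <- matrix(0, nrow(epoch$data), length(centers_i))
  valid <- matrix(FALSE, nrow(epoch$data), length(centers_i))
  for (ch in seq_len(nrow(epoch$data))) {
    w <- masked_window_mean(epoch$data[ch, ], epoch$mask[ch, ], fs,
                            centers_i, half_n)
    ok <- w$n > 0
    vals[ch, ok] <- w$mean[ok]
    valid[ch, ] <- ok
  }
  new_series(vals, valid, epoch$start_s + (centers_i - 1) / fs,
             frame_dt_s, epoch$labels, "signal")
}

#' Extract rectified power depressions with a first-derivative kernel
#'
#' Cross-correlates each channel's envelope (or near-DC signal) with an odd
#' piecewise-constant kernel: +1 over the trailing (past) half-window and -1
#' over the leading (future) half-window, each `kernel_width_s / 2` long, so
#' a falling edge - the onset of a power depression - produces a large
#' positive peak. The output is normalized by the half-window frame count
#' (a unit downward step peaks at ~1 regardless of sampling) and rectified:
#' negative values (rising edges) are zeroed. Frames are valid only where
#' the full kernel lies on valid input frames.
#'
#' @param series An `sd_series` (envelope, or signal for near-DC).
#' @param kernel_width_s Total kernel width (default 300 s = 5 min).
#' @return An `sd_series` of kind `"depression"`; the unrectified values are
#'   kept in field `raw`.
#' @export
depression_xcorr <- function(series, kernel_width_s = 300) {
  stopifnot(inherits(series, "sd_series"))
  h <- round(kernel_width_s / 2 / series$frame_dt)
  nf <- ncol(series$values)
  if (h < 1 || nf < 2 * h) {
    return(new_series(matrix(0, nrow(series$values), 0),
                      matrix(FALSE, nrow(series$values), 0),
                      numeric(0), series$frame_dt, series$labels,
                      "depression"))
  }
  # kernel support: past frames [c-h, c-1] (+1), future frames [c, c+h-1] (-1)
  centers <- seq(h + 1L, nf - h + 1L)
  raw <- matrix(0, nrow(series$values), length(centers))
  valid <- matrix(FALSE, nrow(series$values), length(centers))
  for (ch in seq_len(nrow(series$values))) {
    cx <- cumsum(series$values[ch, ])
    past <- cx[centers - 1L] - cum_at(cx, centers - h - 1L)
    futr <- cx[centers + h - 1L] - cx[centers - 1L]
    raw[ch, ] <- (past - futr) / h
    cv <- cumsum(as.numeric(series$valid[ch, ]))
    nvalid <- cv[centers + h - 1L] - cum_at(cv, centers - h - 1L)
    valid[ch, ] <- nvalid == 2 * h
  }
  raw[!valid] <- 0
  out <- new_series(pmax(raw, 0), valid, series$times[centers],
                    series$frame_dt, series$labels, "depression")
  out$raw <- raw
  out
}

# cumulative-sum lookup with zero before the first element
cum_at <- function(cx, i) ifelse(i >= 1, cx[pmax(i, 1L)], 0)
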