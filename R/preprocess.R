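#' EEG frequency bands used for spreading-depolarization detection
#'
#' Band edges in Hz: near-DC `[0.001, 0.01]` (slow potential changes), Delta
#' `[0.5, 4]`, Theta `[4, 8]`, Alpha `[8, 12]`, Beta `[12, 30]`.
#' @export
sd_bands <- list(
  nearDC = c(0.001, 0.01),
  delta  = c(0.5, 4),
  theta  = c(4, 8),
  alpha  = c(8, 12),
  beta   = c(12, 30)
)

# zero-phase filtering with a linear-phase (symmetric) FIR: filter with
# order/2 padding, then drop the group delay
fir_zerophase <- function(b, x) {
  d <- (length(b) - 1L) %/% 2L
  y <- signal::fftfilt(b, c(x, numeric(d)))
  y[(d + 1L):(d + length(x))]
}

#' Band-pass filter and downsample a recording
#'
#' Applies a zero-phase Hamming-windowed sinc FIR band-pass (order 1000) at
#' the input rate, then decimates to `fs_out` (default 64 Hz; the 30 Hz upper
#' cutoff of the widest band already protects the 64 Hz rate, so no extra
#' anti-alias stage is used). The validity mask is decimated by logical AND
#' over each decimation window. The near-DC band cannot reach its ~0.02 Hz
#' transition bandwidth at the raw rate with order 1000; that band is
#' band-passed at the downsampled rate with the order scaled to the same
#' transition-width target.
#'
#' @param rec An `sd_recording`.
#' @param band One of `names(sd_bands)`.
#' @param fs_out Output sampling rate (Hz).
#' @param order FIR filter order for the bands at the raw rate.
#' @return A filtered, downsampled `sd_recording` with `band` set.
#' @export
bandpass_downsample <- function(rec, band = "delta", fs_out = 64,
                                order = 1000) {
  stopifnot(inherits(rec, "sd_recording"))
  if (!band %in% names(sd_bands)) {
    stop("unknown band '", band, "'; expected one of: ",
         paste(names(sd_bands), collapse = ", "))
  }
  edges <- sd_bands[[band]]
  if (rec$fs < 2 * edges[2]) stop("sampling rate below twice the band edge")
  dec <- rec$fs / fs_out
  if (abs(dec - round(dec)) > 1e-9) {
    stop("input rate must be an integer multiple of fs_out")
  }
  dec <- as.integer(round(dec))

  if (band == "nearDC") {
    # low-pass + decimate first, then a long FIR at the 64 Hz rate
    b1 <- signal::fir1(order, 30 / (rec$fs / 2), type = "low")
    n2 <- 2L * ceiling(3.3 / 0.02 * fs_out / 2)   # Hamming transition ~0.02 Hz
    b2 <- signal::fir1(n2, edges / (fs_out / 2), type = "pass")
    filt <- function(x) {
      y <- fir_zerophase(b1, x)[seq(1, length(x), by = dec)]
      fir_zerophase(b2, y)
    }
  } else {
    b <- signal::fir1(order, edges / (rec$fs / 2), type = "pass")
    filt <- function(x) fir_zerophase(b, x)[seq(1, length(x), by = dec)]
  }

  n_out <- length(seq(1, ncol(rec$data), by = dec))
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) out[ch, ] <- filt(rec$data[ch, ])
  # AND-decimate the mask over each decimation window (pad tail with TRUE)
  msk <- matrix(TRUE, nrow(rec$mask), n_out)
  n_in <- ncol(rec$mask)
  pad <- n_out * dec - n_in
  for (ch in seq_len(nrow(rec$mask))) {
    v <- c(rec$mask[ch, ], rep(TRUE, pad))
    msk[ch, ] <- colSums(matrix(v, nrow = dec)) == dec
  }
  new_recording(out, fs = fs_out, labels = rec$labels,
                dhc_side = rec$dhc_side, mask = msk,
                impedance = rec$impedance, band = band)
}

#' Mask poor-contact segments using electrode impedance
#'
#' The 1 Hz impedance series of each electrode is upsampled to the EEG rate
#' by sample-and-hold; samples whose impedance exceeds twice the channel's
#' median impedance over the whole recording are masked out (data set to the
#' dummy value 0, mask set to `FALSE`). The time axis is never cut. A channel
#' whose median impedance is 0 carries no usable contact-quality information
#' and is masked entirely, with a warning.
#'
#' @param rec An `sd_recording` with an `impedance` matrix.
#' @return The masked `sd_recording`.
#' @export
impedance_mask <- function(rec) {
  stopifnot(inherits(rec, "sd_recording"))
  if (is.null(rec$impedance)) stop("recording has no impedance series")
  n <- ncol(rec$data)
  for (ch in seq_len(nrow(rec$data))) {
    imp <- rec$impedance[ch, ]
    med <- stats::median(imp)
    if (med <= 0) {
      warning("channel ", rec$labels[ch],
              ": non-positive median impedance; whole channel masked")
      rec$mask[ch, ] <- FALSE
      next
    }
    # sample-and-hold to the EEG rate
    idx <- pmin(length(imp), floor((seq_len(n) - 1) / rec$fs) + 1L)
    bad <- imp[idx] > 2 * med
    rec$mask[ch, bad] <- FALSE
  }
  rec$data[!rec$mask] <- 0
  rec
}

#' Mask amplitude outliers with Tukey's fences
#'
#' Per channel, quartiles are computed over the currently valid samples
#' (linear-interpolation quantiles) and samples outside
#' `[Q1 - k (Q3 - Q1), Q3 + k (Q3 - Q1)]` are masked and zeroed. The default
#' `k = 3` targets Tukey's "far out" points, removing high-amplitude
#' artifacts that survive earlier cleaning.
#'
#' @param rec An `sd_recording`.
#' @param k Fence multiplier (> 0).
#' @return The masked `sd_recording`.
#' @export
tukey_outlier_mask <- function(rec, k = 3) {
  stopifnot(inherits(rec, "sd_recording"), k > 0)
  for (ch in seq_len(nrow(rec$data))) {
    valid <- rec$mask[ch, ]
    if (!any(valid)) next
    q <- stats::quantile(rec$data[ch, valid], c(0.25, 0.75),
                         names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr
    hi <- q[2] + k * iqr
    bad <- valid & (rec$data[ch, ] < lo | rec$data[ch, ] > hi)
    rec$mask[ch, bad] <- FALSE
  }
  rec$data[!rec$mask] <- 0
  rec
}

#' Run the full preprocessing chain
#'
#' Band-pass filter + downsample, impedance masking, an optional pluggable
#' artifact-removal hook (default: no-op; the slot where e.g. an ICA-based
#' cleaner could be attached), then Tukey outlier masking.
#'
#' @param rec An `sd_recording` at the raw rate.
#' @param band Frequency band label.
#' @param tukey_k Tukey fence multiplier.
#' @param artifact_hook Function `sd_recording -> sd_recording` applied
#'   between impedance and outlier masking.
#' @return A clean, masked 64 Hz `sd_recording`.
#' @export
preprocess <- function(rec, band = "delta", tukey_k = 3,
                       artifact_hook = identity) {
  rec <- bandpass_downsample(rec, band)
  if (!is.null(rec$impedance)) rec <- impedance_mask(rec)
  rec <- artifact_hook(rec)
  tukey_outlier_mask(rec, k = tukey_k)
}
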