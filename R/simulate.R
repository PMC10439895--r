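#' Configuration for the synthetic SD-EEG simulator
#'
#' Describes a synthetic decompressive-hemicraniectomy recording: coloured
#' baseline EEG with a Delta-dominant spectrum and breach-rhythm power
#' asymmetry between hemispheres, a schedule of spreading depolarizations
#' travelling across electrodes as multiplicative power depressions, and
#' ICU-like artifacts (impedance dropouts, amplitude outliers). Defaults
#' emulate the reported phenomenology of severe-TBI DHC recordings: ~80% of
#' baseline power in the Delta band, ipsilateral amplitudes twice the
#' contralateral ones, depressions lasting tens of minutes and travelling at
#' 0.5-8 mm/min.
#'
#' @param duration_s Recording length (s).
#' @param fs Sampling rate (default 256 Hz).
#' @param band_power_uv2 Named per-band baseline variances (microvolt^2) of
#'   the contralateral channels.
#' @param ipsi_gain Amplitude gain of ipsilateral channels (> 1; power
#'   scales with its square).
#' @param dhc_side Hemisphere with the skull defect.
#' @param events Tibble of SD events: `onset_s`, `origin` (electrode),
#'   `speed_mm_min`, `depth` in (0, 1], `duration_s`, `path`
#'   (list-column of ordered electrode labels), `type`.
#' @param impedance_dropout_rate Dropouts per channel-hour.
#' @param impedance_dropout_s Mean dropout duration (s).
#' @param outlier_rate Amplitude-outburst events per channel-hour.
#' @param channels `"all"` (19 channels) or `"ipsilateral"` (only the 11
#'   electrodes the detector uses; cheaper for large simulation batteries).
#' @param seed RNG seed recorded in the output metadata.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration_s = 7200, fs = 256,
                       band_power_uv2 = c(delta = 80, theta = 9,
                                          alpha = 6, beta = 5),
                       ipsi_gain = 2, dhc_side = "right",
                       events = sd_event_schedule(),
                       impedance_dropout_rate = 0,
                       impedance_dropout_s = 600,
                       outlier_rate = 0, channels = "all", seed = 1) {
  channels <- match.arg(channels, c("all", "ipsilateral"))
  stopifnot(duration_s > 0, fs > 0, ipsi_gain >= 1)
  if (nrow(events)) {
    stopifnot(all(events$depth > 0), all(events$depth <= 1))
  }
  structure(
    list(duration_s = duration_s, fs = fs,
         band_power_uv2 = band_power_uv2, ipsi_gain = ipsi_gain,
         dhc_side = dhc_side, events = events,
         impedance_dropout_rate = impedance_dropout_rate,
         impedance_dropout_s = impedance_dropout_s,
         outlier_rate = outlier_rate, channels = channels, seed = seed),
    class = "sim_config"
  )
}

#' SD event schedules for the simulator
#'
#' `sd_event_schedule()` builds an event table; the default is a single
#' isolated SD starting at Fp2 45 min in, travelling a longitudinal path at
#' 3 mm/min with an 80% power depression lasting 15 min per electrode.
#' `clustered_schedule()` places `n` SDs (>= 3) inside a 3-h interval, the
#' definition of clustered SDs.
#'
#' @param onset_s,origin,speed_mm_min,depth,duration_s,type Event fields
#'   (vectorized).
#' @param path List of electrode label vectors (default: a longitudinal
#'   path from the origin over the DHC hemisphere).
#' @return Tibble of events.
#' @export
sd_event_schedule <- function(onset_s = 2700, origin = "Fp2",
                              speed_mm_min = 3, depth = 0.8,
                              duration_s = 900,
                              path = NULL, type = "CSD") {
  n <- max(length(onset_s), length(origin))
  if (is.null(path)) {
    path <- lapply(rep_len(origin, n), default_sd_path)
  }
  tibble::tibble(
    onset_s = rep_len(onset_s, n), origin = rep_len(origin, n),
    speed_mm_min = rep_len(speed_mm_min, n),
    depth = rep_len(depth, n), duration_s = rep_len(duration_s, n),
    path = path, type = rep_len(type, n))
}

# anterior-posterior path across the lateral electrodes of the origin's side
default_sd_path <- function(origin) {
  right <- c("Fp2", "F4", "C4", "P4", "O2")
  left <- c("Fp1", "F3", "C3", "P3", "O1")
  side <- if (origin %in% left) left else right
  i <- match(origin, side)
  if (is.na(i)) side <- c(origin, right[-1]) else side <- side[i:length(side)]
  side[seq_len(min(3, length(side)))]
}

#' @rdname sd_event_schedule
#' @param n Number of events (>= 3 within 3 h qualifies as clustered).
#' @param start_s Cluster start time.
#' @param spacing_s Inter-onset spacing (default 45 min, so >= 3 events fit
#'   inside 3 h).
#' @export
clustered_schedule <- function(n = 3, start_s = 1800, spacing_s = 2700,
                               origin = "Fp2", ...) {
  sd_event_schedule(onset_s = start_s + (seq_len(n) - 1) * spacing_s,
                    origin = origin, ...)
}

# coloured Gaussian noise with exact per-band variances, shaped in the
# frequency domain (one FFT pair per channel)
colored_noise <- function(n, fs, band_power) {
  z <- stats::fft(stats::rnorm(n))
  freq <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
  h <- numeric(n)
  for (b in names(band_power)) {
    e <- sd_bands[[b]]
    in_b <- freq >= e[1] & freq < e[2]
    if (!any(in_b)) next
    pw <- sum(Mod(z[in_b])^2) / n^2
    if (pw > 0) h[in_b] <- sqrt(band_power[[b]] / pw)
  }
  Re(stats::fft(z * h, inverse = TRUE)) / n
}

#' Generate baseline DHC-like scalp EEG
#'
#' Per channel, coloured noise is synthesized as a sum of band-limited
#' components with the configured band powers; ipsilateral channels are
#' scaled by the breach-rhythm gain. Impedance is a constant 5 kOhm plus
#' measurement jitter, with Poisson-scheduled dropout intervals of
#' elevated impedance when configured. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param montage An [montage_1020()].
#' @return An `sd_recording` (band `"broadband"`).
#' @export
gen_baseline <- function(cfg, montage) {
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  ipsi <- ipsilateral_subset(montage, cfg$dhc_side)
  labels <- if (identical(cfg$channels, "ipsilateral")) ipsi else
    montage$labels
  data <- matrix(0, length(labels), n)
  for (ch in seq_along(labels)) {
    x <- colored_noise(n, cfg$fs, cfg$band_power_uv2)
    if (labels[ch] %in% ipsi) x <- x * cfg$ipsi_gain
    data[ch, ] <- x
  }
  imp <- matrix(5 + 0.05 * stats::rnorm(length(labels) * ceiling(cfg$duration_s)),
                length(labels), ceiling(cfg$duration_s))
  if (cfg$impedance_dropout_rate > 0) {
    for (ch in seq_along(labels)) {
      k <- stats::rpois(1, cfg$impedance_dropout_rate * cfg$duration_s / 3600)
      if (k == 0) next
      at <- sort(stats::runif(k, 0, cfg$duration_s))
      for (t0 in at) {
        len <- stats::rexp(1, 1 / cfg$impedance_dropout_s)
        i0 <- max(1, ceiling(t0)); i1 <- min(ncol(imp), ceiling(t0 + len))
        imp[ch, i0:i1] <- imp[ch, i0:i1] * 5
      }
    }
  }
  if (cfg$outlier_rate > 0) {
    for (ch in seq_along(labels)) {
      k <- stats::rpois(1, cfg$outlier_rate * cfg$duration_s / 3600)
      if (k == 0) next
      at <- sort(stats::runif(k, 0, cfg$duration_s - 1))
      for (t0 in at) {
        i0 <- round(t0 * cfg$fs) + 1
        i1 <- min(n, i0 + cfg$fs)       # 1-s burst
        data[ch, i0:i1] <- data[ch, i0:i1] + 50 * stats::sd(data[ch, ]) *
          sin(2 * pi * 2 * seq(0, by = 1 / cfg$fs, length.out = i1 - i0 + 1))
      }
    }
  }
  new_recording(data, fs = cfg$fs, labels = labels,
                dhc_side = cfg$dhc_side, impedance = imp)
}

#' Inject a travelling SD power depression into a recording
#'
#' For each electrode on the event's path the signal envelope is multiplied
#' by `1 - depth * w(t)`, where `w` is a smooth unimodal (Hann) window of
#' the configured duration delayed by great-circle distance from the origin
#' divided by the propagation speed - a power depression sweeping across
#' the scalp. The emitted annotation carries the onset at the origin plus
#' the per-electrode trough times for round-trip checks.
#'
#' @param rec An `sd_recording` (raw baseline).
#' @param event One row of an [sd_event_schedule()] table.
#' @param montage An [montage_1020()].
#' @return List `recording`, `annotation` (one-row tibble with list-column
#'   `electrode_trough_s`).
#' @export
inject_sd <- function(rec, event, montage) {
  path <- event$path[[1]]
  stopifnot(all(path %in% rec$labels))
  n <- ncol(rec$data)
  tt <- seq(0, by = 1 / rec$fs, length.out = n)
  troughs <- numeric(length(path))
  for (j in seq_along(path)) {
    el <- path[j]
    d_mm <- great_circle_mm(montage, event$origin, el)
    delay_s <- d_mm / event$speed_mm_min * 60
    t0 <- event$onset_s + delay_s
    troughs[j] <- t0 + event$duration_s / 2
    in_w <- tt >= t0 & tt < t0 + event$duration_s
    if (!any(in_w)) next
    w <- 0.5 - 0.5 * cos(2 * pi * (tt[in_w] - t0) / event$duration_s)
    ch <- match(el, rec$labels)
    rec$data[ch, in_w] <- rec$data[ch, in_w] * (1 - event$depth * w)
  }
  list(recording = rec,
       annotation = tibble::tibble(
         onset_s = event$onset_s, type = event$type,
         origin = event$origin, speed_mm_min = event$speed_mm_min,
         depth = event$depth, duration_s = event$duration_s,
         path = list(path), electrode_trough_s = list(troughs)))
}

#' Simulate a full synthetic SD-EEG recording
#'
#' Baseline generation plus injection of every scheduled SD event.
#'
#' @param cfg A [sim_config()].
#' @param montage An [montage_1020()].
#' @return List `recording`, `annotations` (tibble, one row per SD) and
#'   `meta` (the config, including the seed).
#' @examples
#' cfg <- sim_config(duration_s = 600, events = sd_event_schedule()[0, ])
#' sim <- simulate_recording(cfg, montage_1020())
#' @export
simulate_recording <- function(cfg, montage = montage_1020()) {
  rec <- gen_baseline(cfg, montage)
  anns <- list()
  if (nrow(cfg$events)) {
    for (i in seq_len(nrow(cfg$events))) {
      res <- inject_sd(rec, cfg$events[i, ], montage)
      rec <- res$recording
      anns[[i]] <- res$annotation
    }
  }
  annotations <- if (length(anns)) dplyr::bind_rows(anns) else
    tibble::tibble(onset_s = numeric(), type = character())
  list(recording = rec, annotations = annotations, meta = cfg)
}
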