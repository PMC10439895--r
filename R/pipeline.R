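#' Default run configuration
#'
#' All tunable constants of the detector and evaluation framework in one
#' nested list; every entry carries its default next to it. Thresholds
#' Thr1-Thr4 are the learnable parameters (defaults are the
#' cross-validation optima); everything else is a fixed design constant.
#' Configurations round-trip losslessly through [save_config()] /
#' [load_config()] (YAML).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    band = "delta",
    thresholds = list(
      thr1 = 0.3,    # depression-level threshold in [0,1]
      thr2 = 0.6,    # EPM (effective propagation) threshold in [0,1]
      thr3_min = 2,  # temporal neighbourhood half-width, minutes
      thr4 = 0.69    # temporal-consistency fraction in [0,1]
    ),
    geometry = list(
      head_radius_mm = 75,
      grid_rows = 32, grid_cols = 64,
      sigma_mm = 26.2,          # Gaussian interpolation width on the scalp
      neighbor_radius_mm = 70,  # OBBox spatial neighbourhood
      speed_range_mm_min = c(0.5, 8)
    ),
    frames = list(
      frame_dt_s = 30,          # temporal subsampling of binary images
      env_dt_s = 10,            # envelope sampling interval
      env_win_s = 300,          # RMS window (5 min)
      kernel_width_s = 300,     # depression kernel width (5 min)
      stitch_s = 120            # tracker stitching window (2 min)
    ),
    epoch = list(epoch_s = 14400, step_s = 10800,
                 min_island_s = 1200, isolation_s = 60),
    # temporal_smooth: rolling-mean window (frames) applied to the binary
    # images before flow estimation; ~the boundary-flip period of a 3 mm/min
    # wavefront on the subsampled grid, so slow motion registers every frame
    flow = list(alpha = 1, n_iter = 100, preblur_sigma = 0.5,
                temporal_smooth = 9),

    evaluation = list(wl_s = 120, dw_s = 30, dt_s = 3600, q_min = 6,
                      bootstrap_b = 100,
                      thr_tpr = seq(0.5, 0.85, by = 0.05), min_ppv = 0.5),
    frequency = list(window_h = 30, step_h = 1, min_good_h = 20,
                     min_electrodes = 5, min_run_min = 20,
                     isolation_h = 4, stitch_h = 4),
    grid_search = list(thr1 = seq(0.1, 0.5, by = 0.1),
                       thr2 = seq(0.2, 0.8, by = 0.2),
                       thr3_min = c(1, 2, 4),
                       thr4 = seq(0.3, 0.9, by = 0.2)),
    tukey_k = 3,
    seed = 1
  )
}

#' @rdname default_config
#' @param config A configuration list.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
load_config <- function(path) {
  yaml::read_yaml(path)
}

get_cfg <- function(config, ...) {
  keys <- c(...)
  node <- config
  for (k in keys) {
    if (is.null(node[[k]])) {
      stop("missing configuration key: ", paste(keys, collapse = "$"))
    }
    node <- node[[k]]
  }
  node
}

#' Run the full SD detection pipeline on a recording
#'
#' Preprocesses the recording (band-pass + downsample, impedance and Tukey
#' masking), then per 240-min epoch: isolated-island masking, RMS envelope
#' (or frame-averaged signal for the near-DC band), first-derivative
#' depression extraction, cylindrical projection, Gaussian interpolation,
#' three-stage thresholding, 30-s/spatial subsampling, Horn-Schunck optical
#' flow with spherical mapping, OBBox extraction and scoring, and
#' stitching. Epoch outputs are merged onto one 30-s frame grid (a frame is
#' detected if any overlapping epoch detects it).
#'
#' @param rec A raw `sd_recording` (e.g. from [simulate_recording()] or
#'   [read_recording()]).
#' @param config Configuration list (see [default_config()]).
#' @param montage An [montage_1020()]; built from the config's head radius
#'   when `NULL`.
#' @param preprocessed Set `TRUE` when `rec` is already band-passed and
#'   masked.
#' @param verbose Log per-epoch progress.
#' @return A list of class `sd_run`: `detection` (an `sd_detection` on the
#'   global frame grid), `quality` (ipsilateral unmasked-electrode counts)
#'   and `epochs` (per-epoch detections).
#' @export
run_detect <- function(rec, config = default_config(), montage = NULL,
                       preprocessed = FALSE, verbose = FALSE) {
  if (is.null(montage)) {
    montage <- montage_1020(get_cfg(config, "geometry", "head_radius_mm"))
  }
  band <- get_cfg(config, "band")
  thr <- get_cfg(config, "thresholds")
  geo <- get_cfg(config, "geometry")
  frm <- get_cfg(config, "frames")
  epo <- get_cfg(config, "epoch")
  flw <- get_cfg(config, "flow")
  if (!preprocessed) {
    rec <- preprocess(rec, band = band, tukey_k = get_cfg(config, "tukey_k"))
  }
  quality <- quality_series(rec, montage, dt_s = frm$frame_dt_s)
  grid <- pixel_grid(geo$grid_rows, geo$grid_cols)
  if (!any(rec$mask)) {
    warning("recording fully masked; empty detection")
    times <- seq(0, rec_duration_s(rec) - frm$frame_dt_s,
                 by = frm$frame_dt_s)
    det <- structure(list(
      trace = tibble::tibble(time_s = times, detected = 0L),
      runs = tibble::tibble(start_s = numeric(), end_s = numeric(),
                            mean_speed_mm_min = numeric()),
      frame_dt = frm$frame_dt_s, boxes = NULL), class = "sd_detection")
    return(structure(list(detection = det, quality = quality,
                          epochs = list()), class = "sd_run"))
  }
  epochs <- epoch_and_normalize(rec, epo$epoch_s, epo$step_s)
  epoch_dets <- list()
  for (ep in epochs) {
    t0 <- Sys.time()
    ep <- mask_isolated_intervals(ep, epo$min_island_s, epo$isolation_s)
    series <- if (band == "nearDC") {
      signal_series(ep, frame_dt_s = frm$env_dt_s)
    } else {
      rms_envelope(ep, win_s = frm$env_win_s, frame_dt_s = frm$env_dt_s)
    }
    dep <- depression_xcorr(series, kernel_width_s = frm$kernel_width_s)
    if (ncol(dep$values) < 2) next
    topo <- project_frames(dep, montage, grid, dhc_side = rec$dhc_side)
    topo <- interpolate_frames(topo, montage, sigma_mm = geo$sigma_mm)
    topo <- threshold_frames(topo, thr1 = thr$thr1)
    topo <- subsample_frames(topo, montage, frame_dt_s = frm$frame_dt_s)
    nf <- dim(topo$frames)[3]
    # temporally smoothed copies of the binary frames feed the flow
    # estimator; components and thresholds still use the binary frames
    tw <- flw$temporal_smooth
    if (is.null(tw)) tw <- 1L
    smx <- rolling_mean_frames(topo$frames, tw)
    boxes <- list()
    for (f in seq_len(nf - 1)) {
      if (sum(topo$frames[, , f]) == 0) next
      fl <- optical_flow(smx[, , f], smx[, , f + 1],
                         alpha = flw$alpha, n_iter = flw$n_iter,
                         preblur_sigma = flw$preblur_sigma)
      vsph <- map_to_sphere(fl, topo$grid, montage)
      boxes[[length(boxes) + 1L]] <- make_obboxes(
        topo$frames[, , f], vsph, thr2 = thr$thr2, frame = f,
        grid = topo$grid, montage = montage,
        frame_dt_s = frm$frame_dt_s)
    }
    boxes <- if (length(boxes)) dplyr::bind_rows(boxes) else
      make_obboxes(matrix(0, 2, 2), list(vx = matrix(0, 2, 2),
                                         vy = matrix(0, 2, 2)),
                   grid = topo$grid, montage = montage)
    boxes <- score_obboxes(boxes, montage,
                           radius_mm = geo$neighbor_radius_mm,
                           thr3_min = thr$thr3_min, thr4 = thr$thr4,
                           speed_range = geo$speed_range_mm_min,
                           frame_dt_s = frm$frame_dt_s)
    det <- stitch_detections(boxes, topo$times,
                             frame_dt_s = frm$frame_dt_s,
                             stitch_s = frm$stitch_s)
    epoch_dets[[length(epoch_dets) + 1L]] <- det
    if (verbose) {
      message(sprintf("epoch @%.0f min: %d boxes, %d runs, %.1f s",
                      ep$start_s / 60, nrow(boxes), nrow(det$runs),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  detection <- merge_epoch_detections(epoch_dets, rec_duration_s(rec),
                                      frm$frame_dt_s)
  structure(list(detection = detection, quality = quality,
                 epochs = epoch_dets), class = "sd_run")
}

# centred rolling mean along the third (time) axis of a frame stack
rolling_mean_frames <- function(arr, w) {
  if (w <= 1) return(arr)
  nf <- dim(arr)[3]
  half <- (w - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (f in seq_len(nf)) {
    idx <- max(1L, f - half):min(nf, f + half)
    acc <- arr[, , idx[1]]
    for (i in idx[-1]) acc <- acc + arr[, , i]
    out[, , f] <- acc / length(idx)
  }
  out
}

# OR-merge epoch detections onto one global 30-s frame grid
merge_epoch_detections <- function(dets, duration_s, frame_dt_s) {
  times <- seq(0, max(frame_dt_s, duration_s - frame_dt_s), by = frame_dt_s)
  detected <- integer(length(times))
  all_runs <- list()
  for (d in dets) {
    idx <- round(d$trace$time_s / frame_dt_s) + 1L
    ok <- idx >= 1 & idx <= length(times)
    detected[idx[ok]] <- pmax(detected[idx[ok]], d$trace$detected[ok])
    if (nrow(d$runs)) all_runs[[length(all_runs) + 1L]] <- d$runs
  }
  runs <- run_table(detected > 0, times, frame_dt_s)
  runs$mean_speed_mm_min <- rep(NA_real_, nrow(runs))
  if (length(all_runs)) {
    src <- dplyr::bind_rows(all_runs)
    for (i in seq_len(nrow(runs))) {
      ov <- src$end_s > runs$start_s[i] & src$start_s < runs$end_s[i]
      sp <- src$mean_speed_mm_min[ov]
      if (any(is.finite(sp))) runs$mean_speed_mm_min[i] <- mean(sp, na.rm = TRUE)
    }
  }
  structure(list(
    trace = tibble::tibble(time_s = times, detected = detected),
    runs = runs, frame_dt = frame_dt_s, boxes = NULL),
    class = "sd_detection")
}

#' @export
print.sd_run <- function(x, ...) {
  print(x$detection)
  invisible(x)
}

#' Evaluate a detection run against annotations
#'
#' Wraps [label_windows()] and [perf()] using the configuration's
#' evaluation constants.
#'
#' @param run An `sd_run` from [run_detect()] (or an `sd_detection`).
#' @param onsets_s Annotated SD onsets (s).
#' @param config Configuration list.
#' @return List `windows` (labelled window tibble) and `perf` (`sd_perf`).
#' @export
run_evaluate <- function(run, onsets_s, config = default_config()) {
  ev <- get_cfg(config, "evaluation")
  detection <- if (inherits(run, "sd_run")) run$detection else run
  quality <- if (inherits(run, "sd_run")) run$quality else NULL
  windows <- label_windows(detection, onsets_s, quality,
                           wl_s = ev$wl_s, dw_s = ev$dw_s,
                           dt_s = ev$dt_s, q_min = ev$q_min)
  list(windows = windows, perf = perf(windows))
}

#' Threshold grid search over patients
#'
#' Runs the detector over every combination of the configured Thr1-Thr4
#' grids for every patient and tabulates window counts - the input of
#' [l2o_cv()]. Folds are independent, so results do not depend on patient
#' order.
#'
#' @param patients Named list; each element has `recording` (an
#'   `sd_recording`, already preprocessed or raw) and `onsets_s`.
#' @param config Configuration list; `config$grid_search` defines the grid.
#' @param preprocessed Whether the recordings are already preprocessed.
#' @param verbose Log progress.
#' @return Tibble with one row per patient x parameter set (`patient`,
#'   `param_id`, `thr1`, `thr2`, `thr3_min`, `thr4`, window counts).
#' @export
detect_grid <- function(patients, config = default_config(),
                        preprocessed = FALSE, verbose = FALSE) {
  if (!length(patients)) stop("empty patient list")
  gs <- get_cfg(config, "grid_search")
  combos <- expand.grid(thr1 = gs$thr1, thr2 = gs$thr2,
                        thr3_min = gs$thr3_min, thr4 = gs$thr4,
                        KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (p in names(patients)) {
    rec <- patients[[p]]$recording
    if (!preprocessed) {
      rec <- preprocess(rec, band = get_cfg(config, "band"),
                        tukey_k = get_cfg(config, "tukey_k"))
    }
    for (ci in seq_len(nrow(combos))) {
      cfg <- config
      cfg$thresholds$thr1 <- combos$thr1[ci]
      cfg$thresholds$thr2 <- combos$thr2[ci]
      cfg$thresholds$thr3_min <- combos$thr3_min[ci]
      cfg$thresholds$thr4 <- combos$thr4[ci]
      run <- run_detect(rec, cfg, preprocessed = TRUE)
      ev <- run_evaluate(run, patients[[p]]$onsets_s, cfg)$perf
      out[[length(out) + 1L]] <- tibble::tibble(
        patient = p, param_id = ci,
        thr1 = combos$thr1[ci], thr2 = combos$thr2[ci],
        thr3_min = combos$thr3_min[ci], thr4 = combos$thr4[ci],
        n_sd = ev$n_sd, n_detected = ev$n_detected,
        n_fa = ev$n_fa, n_tn = ev$n_tn)
      if (verbose) message(p, " combo ", ci, "/", nrow(combos))
    }
  }
  dplyr::bind_rows(out)
}

#' @rdname detect_grid
#' @param ... Passed to [detect_grid()].
#' @export
run_cv <- function(patients, config = default_config(), ...) {
  tab <- detect_grid(patients, config, ...)
  ev <- get_cfg(config, "evaluation")
  l2o_cv(tab, thr_tpr = ev$thr_tpr, min_ppv = ev$min_ppv)
}

#' SD-frequency analysis of a detection run
#'
#' Builds 30-h frequency windows (quality-gated), prunes/stitches the
#' detections at the 4-h scale and fits the square-root regression of
#' detection duration on SD count.
#'
#' @param run An `sd_run` (or `sd_detection`).
#' @param onsets_s Annotated SD onsets (s).
#' @param config Configuration list.
#' @return List `windows` (tibble incl. `xhat`) and `fit` (`sqrt_fit`).
#' @export
run_frequency <- function(run, onsets_s, config = default_config()) {
  fq <- get_cfg(config, "frequency")
  detection <- if (inherits(run, "sd_run")) run$detection else run
  quality <- if (inherits(run, "sd_run")) run$quality else NULL
  w <- frequency_windows(detection, onsets_s, quality,
                         window_h = fq$window_h, step_h = fq$step_h,
                         min_good_h = fq$min_good_h,
                         min_electrodes = fq$min_electrodes,
                         min_run_min = fq$min_run_min,
                         isolation_h = fq$isolation_h,
                         stitch_h = fq$stitch_h)
  w <- dplyr::filter(w, .data$quality_ok)
  fit <- fit_sqrt(w, "x", "y")
  w$xhat <- sqrt_inverse(w$y, fit$a, fit$b)
  list(windows = w, fit = fit)
}
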