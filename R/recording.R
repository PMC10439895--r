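#' Multichannel scalp EEG recording container
#'
#' Bundles an EEG data matrix with its validity mask, per-electrode impedance
#' series, sampling rate and hemicraniectomy side. Masked samples always hold
#' the dummy value 0 and are excluded from every downstream computation;
#' masking never cuts the time axis, so annotations stay aligned.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling frequency in Hz.
#' @param labels Channel labels (length `nrow(data)`).
#' @param dhc_side `"left"` or `"right"`: hemisphere with the skull defect.
#' @param mask Logical matrix, same shape as `data`; `TRUE` = valid sample.
#' @param impedance Optional channels x seconds matrix of electrode impedances
#'   (kOhm) sampled at 1 Hz.
#' @param band Label of the current band-pass state (`"broadband"` before
#'   filtering).
#' @return An `sd_recording` object.
#' @export
new_recording <- function(data, fs, labels, dhc_side,
                          mask = NULL, impedance = NULL, band = "broadband") {
  data <- as.matrix(data)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(data), ncol(data))
  stopifnot(length(labels) == nrow(data),
            all(dim(mask) == dim(data)),
            fs > 0)
  dhc_side <- match.arg(dhc_side, c("left", "right"))
  if (!is.null(impedance)) {
    impedance <- as.matrix(impedance)
    stopifnot(nrow(impedance) == nrow(data))
  }
  data[!mask] <- 0
  rownames(data) <- rownames(mask) <- labels
  structure(
    list(data = data, fs = fs, labels = as.character(labels),
         mask = mask, impedance = impedance, dhc_side = dhc_side,
         band = band),
    class = "sd_recording"
  )
}

#' @export
print.sd_recording <- function(x, ...) {
  cat(sprintf("<sd_recording> %d ch x %d samples @ %g Hz, band=%s, DHC=%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$band, x$dhc_side))
  cat(sprintf("  valid samples: %.1f%%\n", 100 * mean(x$mask)))
  invisible(x)
}

rec_duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Read / write the plain-text recording container
#'
#' The on-disk container is a directory holding `data.tsv` (channels in
#' columns, samples in rows), `mask.tsv`, optionally `impedance.tsv` (1 Hz),
#' a JSON sidecar `meta.json` (labels, fs, dhc_side, band) and optionally
#' `annotations.tsv` (columns `onset_s`, `type`).
#'
#' @param rec An `sd_recording`.
#' @param path Directory to write to / read from.
#' @param annotations Optional annotation tibble with columns `onset_s`,
#'   `type`.
#' @return `read_recording()` returns a list with elements `recording` and
#'   `annotations` (`NULL` if absent).
#' @export
write_recording <- function(rec, path, annotations = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, f) {
    if (is.null(rownames(m))) rownames(m) <- rec$labels
    utils::write.table(t(m), file.path(path, f), sep = "\t",
                       row.names = FALSE, col.names = rownames(m))
  }
  write_mat(rec$data, "data.tsv")
  write_mat(rec$mask * 1L, "mask.tsv")
  if (!is.null(rec$impedance)) write_mat(rec$impedance, "impedance.tsv")
  jsonlite::write_json(
    list(labels = rec$labels, fs = rec$fs, dhc_side = rec$dhc_side,
         band = rec$band),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(annotations)) {
    utils::write.table(annotations, file.path(path, "annotations.tsv"),
                       sep = "\t", row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  read_mat <- function(f) {
    t(as.matrix(utils::read.delim(file.path(path, f), check.names = FALSE)))
  }
  data <- read_mat("data.tsv")
  mask <- read_mat("mask.tsv") > 0
  imp_path <- file.path(path, "impedance.tsv")
  impedance <- if (file.exists(imp_path)) read_mat("impedance.tsv") else NULL
  ann_path <- file.path(path, "annotations.tsv")
  annotations <- if (file.exists(ann_path)) {
    tibble::as_tibble(utils::read.delim(ann_path))
  } else NULL
  rec <- new_recording(data, fs = meta$fs, labels = meta$labels,
                       dhc_side = meta$dhc_side, mask = mask,
                       impedance = impedance, band = meta$band)
  list(recording = rec, annotations = annotations)
}

# per-sample count of unmasked ipsilateral electrodes, on a coarse time grid
# (dt_s spacing); used for Q_avg window gating and 30-h quality screening
quality_series <- function(rec, montage, dt_s = 30) {
  ipsi <- ipsilateral_subset(montage, rec$dhc_side)
  ipsi <- intersect(ipsi, rec$labels)
  n <- ncol(rec$data)
  starts <- seq(1, n, by = max(1L, round(dt_s * rec$fs)))
  counts <- vapply(starts, function(s) {
    e <- min(n, s + round(dt_s * rec$fs) - 1)
    sum(rowMeans(rec$mask[ipsi, s:e, drop = FALSE]) > 0.5)
  }, numeric(1))
  tibble::tibble(time_s = (starts - 1) / rec$fs, n_good = counts)
}
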