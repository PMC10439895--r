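# shared fixtures built in code

toy_montage <- function() montage_1020()

# low-rate recording for epoching / masking logic (fs in Hz)
toy_recording <- function(data, fs = 1, dhc_side = "right",
                          labels = NULL, impedance = NULL) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  new_recording(data, fs = fs, labels = labels, dhc_side = dhc_side,
                impedance = impedance)
}

# hand-built frame series (sd_series) for depression / projection tests
toy_series <- function(values, frame_dt = 10, valid = NULL,
                       labels = NULL, kind = "envelope") {
  values <- as.matrix(values)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(values)))
  sdwave:::new_series(values, valid,
                      seq(0, by = frame_dt, length.out = ncol(values)),
                      frame_dt, labels, kind)
}

# depression series with the 11 right-ipsilateral channels
ipsi_series <- function(values, frame_dt = 10, valid = NULL) {
  labels <- ipsilateral_subset(toy_montage(), "right")
  stopifnot(nrow(as.matrix(values)) == 11)
  toy_series(values, frame_dt, valid, labels, kind = "depression")
}
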