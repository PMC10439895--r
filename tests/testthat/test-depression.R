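test_that("epoching yields 240-min windows at 180-min steps plus a flagged tail", {
  # 600-min recording at 1 Hz
  rec <- toy_recording(matrix(rnorm(36000), 1), fs = 1)
  eps <- epoch_and_normalize(rec)
  starts_min <- vapply(eps, function(e) e$start_s / 60, numeric(1))
  expect_equal(starts_min, c(0, 180, 360, 540))
  expect_equal(vapply(eps, function(e) e$tail, logical(1)),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(ncol(eps[[1]]$data), 240 * 60)
  # recording shorter than one epoch -> single flagged tail
  short <- epoch_and_normalize(toy_recording(matrix(rnorm(600), 1), fs = 1))
  expect_length(short, 1)
  expect_true(short[[1]]$tail)
})

test_that("normalization gives unit variance; constant channels get masked", {
  set.seed(5)
  data <- rbind(rnorm(20000, sd = 2), rep(5, 20000))
  rec <- toy_recording(data, fs = 1)
  expect_warning(eps <- epoch_and_normalize(rec), "zero variance")
  e <- eps[[1]]
  expect_equal(stats::sd(e$data[1, e$mask[1, ]]), 1, tolerance = 0.05)
  expect_true(all(!e$mask[2, ]))
})

test_that("short isolated valid islands are masked; connected or long ones kept", {
  n <- 240 * 60   # one epoch at 1 Hz
  base <- rep(FALSE, n)
  m1 <- base; m1[3001:3600] <- TRUE                       # 10 min, isolated
  m2 <- base; m2[3001:3600] <- TRUE; m2[3631:14400] <- TRUE # 30 s from 3 h run
  m3 <- base; m3[3001:4500] <- TRUE                       # 25 min, isolated
  rec <- toy_recording(matrix(rnorm(3 * n), 3), fs = 1)
  rec$mask <- rbind(m1, m2, m3)
  rec$data[!rec$mask] <- 0
  ep <- epoch_and_normalize(rec)[[1]]
  out <- mask_isolated_intervals(ep)
  expect_true(all(!out$mask[1, 3001:3600]))
  expect_true(all(out$mask[2, 3001:3600]))
  expect_true(all(out$mask[3, 3001:4500]))
})

test_that("RMS envelope of the squared signal is flat for constant amplitude", {
  n <- 240 * 60
  ep <- epoch_and_normalize(toy_recording(matrix(rnorm(n), 1), fs = 1))[[1]]
  a <- 1.7
  ep$data[1, ] <- a * sign(ep$data[1, ])   # constant |amplitude| = a
  env <- rms_envelope(ep, win_s = 300, frame_dt_s = 10)
  vals <- env$values[1, env$valid[1, ]]
  # sqrt(mean((a^2)^2)) = a^2
  expect_equal(mean(vals), a^2, tolerance = 1e-9)
  expect_lt(stats::sd(vals) / mean(vals), 0.01)
})

test_that("an amplitude step produces a monotone envelope transition", {
  n <- 240 * 60
  fs <- 4
  t0 <- 7200   # seconds
  x <- c(rep(1, t0 * fs), rep(0.5, n * fs / 1 - t0 * fs))
  x <- x * sign(rnorm(length(x)))
  ep <- epoch_and_normalize(toy_recording(matrix(rnorm(length(x)), 1),
                                          fs = fs))[[1]]
  ep$data[1, ] <- x
  env <- rms_envelope(ep, win_s = 300, frame_dt_s = 10)
  # brute-force window evaluation across the transition
  trans <- which(env$times >= t0 - 150 & env$times <= t0 + 150)
  expect_true(all(diff(env$values[1, trans]) <= 1e-12))
  half_n <- round(150 * fs)
  for (f in trans[c(1, length(trans) %/% 2, length(trans))]) {
    c0 <- round(env$times[f] * fs) + 1
    idx <- (c0 - half_n):(c0 + half_n)
    # cumulative-sum evaluation agrees with the direct mean up to float
    # cancellation over the 240-min epoch
    expect_equal(env$values[1, f], sqrt(mean(x[idx]^4)), tolerance = 1e-4)
  }
})

test_that("fully masked channels give fully masked envelopes", {
  n <- 240 * 60
  rec <- toy_recording(matrix(rnorm(2 * n), 2), fs = 1)
  rec$mask[2, ] <- FALSE
  rec$data[2, ] <- 0
  ep <- epoch_and_normalize(rec)[[1]]
  env <- rms_envelope(ep)
  expect_true(all(!env$valid[2, ]))
  expect_true(any(env$valid[1, ]))
})

test_that("depression kernel turns a falling edge into a unit peak", {
  nf <- 200
  step_at <- 100
  s <- toy_series(rbind(c(rep(1, step_at - 1), rep(0, nf - step_at + 1)),
                        rep(2, nf)))
  dep <- depression_xcorr(s, kernel_width_s = 300)  # h = 15 frames
  h <- 15
  peak_f <- which(dep$times == s$times[step_at])
  expect_equal(dep$values[1, peak_f], 1)
  # triangular decay on both sides of the step
  expect_equal(dep$values[1, peak_f - 5], 1 - 5 / h)
  expect_equal(dep$values[1, peak_f + 5], 1 - 5 / h)
  # constant input -> all zeros
  expect_true(all(dep$values[2, ] == 0))
  # rising edge -> zero after rectification, negative before
  s_up <- toy_series(matrix(c(rep(0, 99), rep(1, 101)), 1))
  dep_up <- depression_xcorr(s_up)
  expect_true(all(dep_up$values == 0))
  expect_lt(min(dep_up$raw), 0)
})

test_that("unrectified response is linear in the input scale", {
  set.seed(8)
  s <- toy_series(matrix(rnorm(120), 1))
  d1 <- depression_xcorr(s)
  s$values <- 3.7 * s$values
  d2 <- depression_xcorr(s)
  expect_equal(d2$raw, 3.7 * d1$raw, tolerance = 1e-12)
  expect_gte(min(d1$values), 0)
})

test_that("cumulative-sum implementation matches the naive sliding sum", {
  set.seed(9)
  nf <- 180   # 30 min at 10-s frames
  s <- toy_series(matrix(rnorm(nf), 1))
  dep <- depression_xcorr(s, kernel_width_s = 300)
  h <- 15
  for (k in seq_along(dep$times)) {
    c0 <- which(s$times == dep$times[k])
    naive <- (sum(s$values[1, (c0 - h):(c0 - 1)]) -
                sum(s$values[1, c0:(c0 + h - 1)])) / h
    expect_equal(dep$raw[1, k], naive, tolerance = 1e-9)
  }
  # input shorter than the kernel -> empty series
  empty <- depression_xcorr(toy_series(matrix(rnorm(10), 1)))
  expect_equal(ncol(empty$values), 0)
})

test_that("the near-DC path detects falling slow-potential edges", {
  # slow negative shift: the kernel applied to the frame-averaged signal
  # itself (no envelope) yields a positive peak at the falling edge
  n <- 240 * 60
  rec <- toy_recording(matrix(rnorm(n, sd = 0.1), 1), fs = 1)
  ep <- epoch_and_normalize(rec)[[1]]
  drop_at <- 7000
  ep$data[1, ] <- ep$data[1, ] * 0.01 +
    c(rep(1, drop_at), rep(0, n - drop_at))
  s <- signal_series(ep, frame_dt_s = 10)
  dep <- depression_xcorr(s, kernel_width_s = 300)
  peak_t <- dep$times[which.max(dep$values[1, ])]
  expect_lt(abs(peak_t - drop_at), 30)
  expect_gt(max(dep$values[1, ]), 0.9)
})
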