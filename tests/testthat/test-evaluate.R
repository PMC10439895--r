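mk_trace <- function(det_times, t_end = 7200, dt = 30) {
  times <- seq(0, t_end - dt, by = dt)
  tibble::tibble(time_s = times,
                 detected = as.integer(times %in% det_times))
}

test_that("window labelling follows the SD / false-alarm / true-negative rules", {
  # SD at minute 1 of a window, detection 50 min later -> detected SD window
  w <- label_windows(mk_trace(60 + 50 * 60), onsets_s = 60)
  sd_w <- w[w$label == "SD", ]
  expect_true(nrow(sd_w) > 0 && all(sd_w$detected))
  # detection present, nearest SD 80 min away -> false alarm window
  w2 <- label_windows(mk_trace(600), onsets_s = 600 + 80 * 60)
  expect_true(any(w2$label == "FA" & w2$start_s <= 600))
  # empty trace, no SD within an hour of the edges -> true negatives
  w3 <- label_windows(mk_trace(numeric(0)), onsets_s = numeric(0))
  expect_true(all(w3$label == "TN"))
  # windows below the Q_avg quality floor are excluded
  q <- tibble::tibble(time_s = seq(0, 7170, by = 30),
                      n_good = c(rep(3, 60), rep(11, 180)))
  w4 <- label_windows(mk_trace(numeric(0)), onsets_s = numeric(0),
                      quality = q)
  expect_true(all(w4$label[w4$start_s < 1700] == "excluded"))
  expect_true(all(w4$label[w4$start_s > 1900] == "TN"))
})

test_that("window grid matches floor((T - WL)/dW) + 1", {
  for (t_end in c(3600, 5430, 86400)) {
    w <- label_windows(mk_trace(numeric(0), t_end = t_end),
                       onsets_s = numeric(0))
    expect_equal(nrow(w), floor((t_end - 120) / 30) + 1)
  }
})

test_that("TPR/FPR/PPV arithmetic matches the definitions", {
  p <- perf(n_sd = 16685, n_detected = 12303, n_fa = 6339,
            n_tn = 437849 - 6339)
  expect_equal(round(p$tpr, 2), 0.74)
  expect_equal(round(p$fpr, 4), 0.0145)
  expect_equal(p$ppv, 12303 / (12303 + 6339))
  # zero detections: TPR = FPR = 0, PPV reported 0 with undefined flag
  p0 <- perf(n_sd = 10, n_detected = 0, n_fa = 0, n_tn = 100)
  expect_equal(p0$tpr, 0)
  expect_equal(p0$fpr, 0)
  expect_equal(p0$ppv, 0)
  expect_true(p0$ppv_undefined)
  expect_equal(p0$eps_cv, sqrt(2))
  g <- glance(p)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_detected, 12303)
})

test_that("labelled-window metrics equal brute-force recounts on random schedules", {
  set.seed(14)
  for (rep in 1:100) {
    t_end <- 7200
    onsets <- sort(runif(sample(0:3, 1), 0, t_end))
    det_times <- sort(sample(seq(0, t_end - 30, by = 30),
                             sample(0:5, 1)))
    w <- label_windows(mk_trace(det_times, t_end), onsets)
    p <- perf(w)
    # independent interval-scan recount
    starts <- seq(0, t_end - 120, by = 30)
    n_sd <- n_det <- n_fa <- n_tn <- 0
    for (s in starts) {
      sd_in <- onsets[onsets >= s & onsets < s + 120]
      d_in <- det_times[det_times >= s & det_times < s + 120]
      if (length(sd_in)) {
        n_sd <- n_sd + 1
        hit <- FALSE
        for (o in sd_in) {
          if (any(abs(det_times - o) <= 3600)) hit <- TRUE
        }
        n_det <- n_det + hit
      } else if (length(d_in)) {
        near <- FALSE
        for (d in d_in) if (any(abs(onsets - d) <= 3600)) near <- TRUE
        if (!near) n_fa <- n_fa + 1
      } else if (!any(onsets >= s - 3600 & onsets < s + 120 + 3600)) {
        n_tn <- n_tn + 1
      }
    }
    expect_equal(c(p$n_sd, p$n_detected, p$n_fa, p$n_tn),
                 c(n_sd, n_det, n_fa, n_tn))
  }
})

test_that("weighted bootstrap intervals behave and cover", {
  # identical fold values -> degenerate interval
  ci <- bootstrap_ci(rep(0.7, 5), rep(10, 5), seed = 1)
  expect_equal(unname(ci["lower"]), 0.7)
  expect_equal(unname(ci["upper"]), 0.7)
  # two distinct folds -> positive width
  ci2 <- bootstrap_ci(c(0, 1), c(1, 1), seed = 2)
  expect_gt(ci2["upper"] - ci2["lower"], 0)
  # coverage: folds ~ N(0.7, 0.05^2), interval covers 0.7 in >= 90 of 100
  set.seed(15)
  cover <- 0
  for (r in 1:100) {
    vals <- rnorm(66, 0.7, 0.05)
    ci <- bootstrap_ci(vals, rep(1, 66), b = 100)
    cover <- cover + (ci["lower"] <= 0.7 && 0.7 <= ci["upper"])
  }
  expect_gte(cover, 90)
})

# synthetic per-patient, per-parameter-set window-count table
mk_perf_table <- function(n_patients, seed = 16) {
  set.seed(seed)
  tidyr::expand_grid(patient = paste0("p", seq_len(n_patients)),
                     param_id = 1:4) |>
    dplyr::mutate(
      n_sd = 50,
      n_detected = rbinom(dplyr::n(), 50, 0.55 + 0.08 * .data$param_id),
      n_fa = rbinom(dplyr::n(), 1000, 0.005 * .data$param_id),
      n_tn = 1000 - .data$n_fa)
}

test_that("leave-2-out enumerates C(n,2) splits and picks min-FPR params", {
  cv <- l2o_cv(mk_perf_table(12), thr_tpr = c(0.5, 0.6, 0.7))
  expect_equal(cv$n_splits, 66)
  expect_equal(max(cv$folds$fold), 66)
  # per fold and threshold, chosen params have min train FPR among feasible
  expect_true(all(cv$folds$train_tpr >= cv$folds$thr_tpr))
  expect_error(l2o_cv(mk_perf_table(2)), "more than")
  # four patients -> 6 folds
  cv4 <- l2o_cv(mk_perf_table(4), thr_tpr = 0.5)
  expect_equal(cv4$n_splits, 6)
  # bootstrap CIs at the operating point bracket the averaged estimate
  ci <- cv4$optimal_ci
  expect_lte(ci$tpr["lower"], ci$tpr["mean"])
  expect_gte(ci$tpr["upper"], ci$tpr["mean"])
  expect_lte(ci$fpr["lower"], ci$fpr["upper"])
})

test_that("cross-validation error takes its closed-form limits", {
  tbl <- tibble::tibble(patient = rep(c("a", "b", "c"), each = 1),
                        param_id = 1, n_sd = 10, n_detected = 10,
                        n_fa = 0, n_tn = 100)
  cv <- l2o_cv(tbl, thr_tpr = 0.5)
  expect_equal(cv$optimal$eps_cv, 0)   # TPR = PPV = 1
  expect_equal(sqrt((1 - 0)^2 + (1 - 0)^2), sqrt(2))
})

test_that("cross-validation results are invariant to patient order", {
  tbl <- mk_perf_table(6)
  cv1 <- l2o_cv(tbl, thr_tpr = c(0.5, 0.7))
  cv2 <- l2o_cv(tbl[sample(nrow(tbl)), ], thr_tpr = c(0.5, 0.7))
  expect_equal(cv1$roc$tpr, cv2$roc$tpr)
  expect_equal(cv1$roc$fpr, cv2$roc$fpr)
  expect_equal(cv1$optimal$eps_cv, cv2$optimal$eps_cv)
})

test_that("speed summary averages only true-positive runs", {
  det <- structure(list(
    trace = mk_trace(c(600, 5000)),
    runs = tibble::tibble(start_s = c(600, 5000), end_s = c(660, 5060),
                          mean_speed_mm_min = c(3, 7)),
    frame_dt = 30), class = "sd_detection")
  s <- speed_summary(det, onsets_s = c(500, 4800))
  expect_equal(nrow(s), 2)   # both runs within 1 h of an onset
  s2 <- speed_summary(det, onsets_s = 500, dt_s = 600)
  expect_equal(s2$speed_mm_min, 3)
  s3 <- speed_summary(det, onsets_s = numeric(0))
  expect_equal(nrow(s3), 0)
})
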