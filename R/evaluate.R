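#' Label sliding evaluation windows
#'
#' Overlapping windows of width `wl_s` (default 2 min) advancing by `dw_s`
#' (default 30 s) are labelled against the annotated SD onsets:
#' \itemize{
#'   \item SD window: contains an annotated onset; it counts as detected if
#'     any detection lies within `dt_s` (default 1 h) of that onset. The
#'     tolerance reflects the annotation limits: the ECoG strip covers a
#'     small patch while EEG sees the whole hemisphere, and an SD needs tens
#'     of minutes to cross the ~54 mm inter-electrode spacing.
#'   \item False-alarm window: contains a detection with no annotated onset
#'     within `dt_s` of any detected interval inside the window.
#'   \item True-negative window: no detection, and no onset inside the
#'     window or within `dt_s` of either end.
#' }
#' Windows matching none of the rules contribute to no count; windows whose
#' mean number of unmasked ipsilateral electrodes `Q_avg` falls below
#' `q_min` (default 6 of 11) are excluded from everything.
#'
#' @param detection An `sd_detection` (or a tibble with `time_s`,
#'   `detected`).
#' @param onsets_s Numeric vector of annotated SD onset times (s).
#' @param quality Optional tibble (`time_s`, `n_good`) of unmasked
#'   ipsilateral electrode counts; `NULL` disables quality gating.
#' @param wl_s,dw_s,dt_s,q_min Window width, step, matching tolerance
#'   (seconds) and minimum electrode count.
#' @return Tibble: `start_s`, `q_avg`, `label` (`"SD"`, `"FA"`, `"TN"`,
#'   `"none"`, `"excluded"`), `detected`.
#' @export
label_windows <- function(detection, onsets_s, quality = NULL,
                          wl_s = 120, dw_s = 30, dt_s = 3600, q_min = 6) {
  trace <- if (inherits(detection, "sd_detection")) detection$trace else detection
  t_end <- max(trace$time_s) + (trace$time_s[2] - trace$time_s[1])
  starts <- seq(0, t_end - wl_s, by = dw_s)
  det_times <- trace$time_s[trace$detected > 0]
  lab <- character(length(starts))
  det <- logical(length(starts))
  q_avg <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + wl_s
    if (!is.null(quality)) {
      in_w <- quality$time_s >= s & quality$time_s < e
      q_avg[i] <- if (any(in_w)) mean(quality$n_good[in_w]) else 0
      if (q_avg[i] < q_min) { lab[i] <- "excluded"; next }
    }
    sd_in <- onsets_s[onsets_s >= s & onsets_s < e]
    det_in <- det_times[det_times >= s & det_times < e]
    if (length(sd_in)) {
      lab[i] <- "SD"
      det[i] <- length(det_times) > 0 &&
        any(vapply(sd_in, function(o) any(abs(det_times - o) <= dt_s),
                   logical(1)))
    } else if (length(det_in)) {
      near_sd <- any(vapply(det_in, function(d)
        any(abs(onsets_s - d) <= dt_s), logical(1)))
      lab[i] <- if (near_sd) "none" else "FA"
      det[i] <- TRUE
    } else {
      no_sd_near <- !any(onsets_s >= s - dt_s & onsets_s < e + dt_s)
      lab[i] <- if (no_sd_near) "TN" else "none"
    }
  }
  tibble::tibble(start_s = starts, q_avg = q_avg, label = lab,
                 detected = det)
}

#' Windowed detection performance
#'
#' Computes the true positive rate (detected SD windows / SD windows), false
#' positive rate (false-alarm windows / (false-alarm + true-negative
#' windows)) and precision PPV (detected SD windows / (detected SD windows +
#' false-alarm windows)) from labelled windows or from explicit counts.
#'
#' @param windows Tibble from [label_windows()], or `NULL` if counts are
#'   given directly.
#' @param n_sd,n_detected,n_fa,n_tn Window counts (used when `windows` is
#'   `NULL`).
#' @return An `sd_perf` object; `glance()` returns it as a one-row tibble.
#'   With zero detections PPV is reported as 0 with `ppv_undefined = TRUE`.
#' @export
perf <- function(windows = NULL, n_sd = NULL, n_detected = NULL,
                 n_fa = NULL, n_tn = NULL) {
  if (!is.null(windows)) {
    n_sd <- sum(windows$label == "SD")
    n_detected <- sum(windows$label == "SD" & windows$detected)
    n_fa <- sum(windows$label == "FA")
    n_tn <- sum(windows$label == "TN")
  }
  tpr <- if (n_sd > 0) n_detected / n_sd else 0
  fpr <- if (n_fa + n_tn > 0) n_fa / (n_fa + n_tn) else 0
  ppv_undefined <- (n_detected + n_fa) == 0
  ppv <- if (!ppv_undefined) n_detected / (n_detected + n_fa) else 0
  structure(
    list(tpr = tpr, fpr = fpr, ppv = ppv, ppv_undefined = ppv_undefined,
         eps_cv = sqrt((1 - tpr)^2 + (1 - ppv)^2),
         n_sd = n_sd, n_detected = n_detected, n_fa = n_fa, n_tn = n_tn),
    class = "sd_perf"
  )
}

#' @export
print.sd_perf <- function(x, ...) {
  cat(sprintf("<sd_perf> TPR %.4f (%d/%d), FPR %.4f (%d/%d), PPV %.4f%s\n",
              x$tpr, x$n_detected, x$n_sd, x$fpr, x$n_fa, x$n_fa + x$n_tn,
              x$ppv, if (x$ppv_undefined) " (undefined)" else ""))
  invisible(x)
}

#' @export
#' @importFrom generics glance
generics::glance

#' @export
glance.sd_perf <- function(x, ...) {
  tibble::tibble(tpr = x$tpr, fpr = x$fpr, ppv = x$ppv,
                 eps_cv = x$eps_cv, ppv_undefined = x$ppv_undefined,
                 n_sd = x$n_sd, n_detected = x$n_detected,
                 n_fa = x$n_fa, n_tn = x$n_tn)
}

#' Weighted bootstrap confidence interval over folds
#'
#' Resamples fold-level metric values with replacement `b` times, with
#' selection probability proportional to the fold weights (number of SD
#' windows for TPR, non-SD windows for FPR), and returns percentile bounds
#' of the weighted mean.
#'
#' @param values Per-fold metric values.
#' @param weights Per-fold weights.
#' @param b Bootstrap sample size (default 100).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional RNG seed for reproducibility.
#' @return Named vector `lower`, `upper`, `mean`.
#' @export
bootstrap_ci <- function(values, weights = rep(1, length(values)), b = 100,
                         conf = 0.95, seed = NULL) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  stat <- vapply(seq_len(b), function(i) {
    idx <- sample.int(n, n, replace = TRUE, prob = weights)
    stats::weighted.mean(values[idx], weights[idx])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- stats::quantile(stat, c(a, 1 - a), names = FALSE)
  c(lower = ci[1], upper = ci[2],
    mean = stats::weighted.mean(values, weights))
}

#' Leave-2-out cross-validation with ROC threshold averaging
#'
#' Takes a per-patient, per-parameter-set table of window counts (so that
#' the expensive detection sweep runs once, outside the fold loop),
#' enumerates all `C(n, 2)` train/validation splits, and for each split and
#' each candidate TPR threshold picks the parameter set minimizing pooled
#' train FPR subject to pooled train TPR >= threshold, then evaluates it on
#' the two held-out patients. Validation points are threshold-averaged
#' (mean FPR/TPR/PPV across folds at the same TPR threshold) and the
#' operating point is the averaged point with minimum
#' `eps_cv = sqrt((1-TPR)^2 + (1-PPV)^2)` among those with PPV >= `min_ppv`.
#'
#' @param perf_table Tibble with columns `patient`, `param_id` (identifying
#'   a parameter set, e.g. a Thr1..Thr4 combination), `n_sd`, `n_detected`,
#'   `n_fa`, `n_tn`; one row per patient x parameter set.
#' @param thr_tpr Candidate TPR thresholds (default `seq(0.5, 0.85, 0.05)`).
#' @param leave_out Held-out patients per fold (default 2).
#' @param min_ppv PPV floor for the operating point (default 0.5).
#' @return An `sd_cv` object with `folds` (per-fold selections), `roc`
#'   (averaged validation curve), `train_roc`, `optimal` and `optimal_ci`
#'   (weighted bootstrap intervals for TPR and FPR at the operating
#'   point).
#' @export
l2o_cv <- function(perf_table, thr_tpr = seq(0.5, 0.85, by = 0.05),
                   leave_out = 2, min_ppv = 0.5) {
  patients <- unique(perf_table$patient)
  if (length(patients) <= leave_out) {
    stop("need more than ", leave_out, " patients for leave-", leave_out,
         "-out cross-validation")
  }
  splits <- utils::combn(patients, leave_out, simplify = FALSE)
  pooled_perf <- function(tbl) {
    tbl |>
      dplyr::group_by(.data$param_id) |>
      dplyr::summarise(n_sd = sum(.data$n_sd),
                       n_detected = sum(.data$n_detected),
                       n_fa = sum(.data$n_fa), n_tn = sum(.data$n_tn),
                       .groups = "drop") |>
      dplyr::mutate(
        tpr = ifelse(.data$n_sd > 0, .data$n_detected / .data$n_sd, 0),
        fpr = ifelse(.data$n_fa + .data$n_tn > 0,
                     .data$n_fa / (.data$n_fa + .data$n_tn), 0),
        ppv = ifelse(.data$n_detected + .data$n_fa > 0,
                     .data$n_detected / (.data$n_detected + .data$n_fa), 0))
  }
  folds <- list()
  for (k in seq_along(splits)) {
    held <- splits[[k]]
    train <- pooled_perf(dplyr::filter(perf_table,
                                       !.data$patient %in% held))
    val_tbl <- dplyr::filter(perf_table, .data$patient %in% held)
    for (tt in thr_tpr) {
      feasible <- dplyr::filter(train, .data$tpr >= tt)
      if (!nrow(feasible)) next
      best <- feasible[order(feasible$fpr, -feasible$tpr), ][1, ]
      val <- pooled_perf(dplyr::filter(val_tbl,
                                       .data$param_id == best$param_id))
      folds[[length(folds) + 1L]] <- tibble::tibble(
        fold = k, thr_tpr = tt, param_id = best$param_id,
        train_tpr = best$tpr, train_fpr = best$fpr, train_ppv = best$ppv,
        val_tpr = val$tpr, val_fpr = val$fpr, val_ppv = val$ppv,
        val_n_sd = val$n_sd, val_n_nonsd = val$n_fa + val$n_tn)
    }
  }
  if (!length(folds)) stop("no feasible parameter set at any TPR threshold")
  folds <- dplyr::bind_rows(folds)
  skipped <- setdiff(thr_tpr, unique(folds$thr_tpr))
  if (length(skipped)) {
    warning("no feasible parameter set at Thr_TPR = ",
            paste(skipped, collapse = ", "), "; point(s) skipped")
  }
  avg <- function(cols) {
    folds |>
      dplyr::group_by(.data$thr_tpr) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                       n_folds = dplyr::n(), .groups = "drop")
  }
  roc <- avg(c("val_tpr", "val_fpr", "val_ppv")) |>
    dplyr::rename(tpr = "val_tpr", fpr = "val_fpr", ppv = "val_ppv") |>
    dplyr::mutate(eps_cv = sqrt((1 - .data$tpr)^2 + (1 - .data$ppv)^2))
  train_roc <- avg(c("train_tpr", "train_fpr", "train_ppv")) |>
    dplyr::rename(tpr = "train_tpr", fpr = "train_fpr", ppv = "train_ppv")
  eligible <- dplyr::filter(roc, .data$ppv >= min_ppv)
  optimal <- if (nrow(eligible)) {
    eligible[which.min(eligible$eps_cv), ]
  } else {
    roc[which.min(roc$eps_cv), ]
  }
  # weighted bootstrap CIs at the operating point: TPR weighted by SD
  # windows, FPR by non-SD windows, across the folds of that threshold
  at_opt <- dplyr::filter(folds, .data$thr_tpr == optimal$thr_tpr)
  optimal_ci <- list(
    tpr = bootstrap_ci(at_opt$val_tpr, pmax(1, at_opt$val_n_sd), seed = 1),
    fpr = bootstrap_ci(at_opt$val_fpr, pmax(1, at_opt$val_n_nonsd),
                       seed = 2))
  structure(
    list(folds = folds, roc = roc, train_roc = train_roc,
         optimal = optimal, optimal_ci = optimal_ci,
         n_splits = length(splits), thr_tpr = thr_tpr, min_ppv = min_ppv),
    class = "sd_cv"
  )
}

#' @export
print.sd_cv <- function(x, ...) {
  cat(sprintf("<sd_cv> %d splits; optimal: Thr_TPR %.2f, TPR %.3f, FPR %.4f, PPV %.3f, eps %.4f\n",
              x$n_splits, x$optimal$thr_tpr, x$optimal$tpr, x$optimal$fpr,
              x$optimal$ppv, x$optimal$eps_cv))
  invisible(x)
}

#' @export
tidy.sd_cv <- function(x, ...) x$roc

#' @export
glance.sd_cv <- function(x, ...) {
  tibble::tibble(n_splits = x$n_splits, thr_tpr = x$optimal$thr_tpr,
                 tpr = x$optimal$tpr, fpr = x$optimal$fpr,
                 ppv = x$optimal$ppv, eps_cv = x$optimal$eps_cv)
}

#' Propagation-speed summary of true detections
#'
#' For each detection run lying within `dt_s` of an annotated onset, the
#' mean spherical optical-flow speed of its member OBBoxes (mm/min).
#'
#' @param detection An `sd_detection` with a `runs` table.
#' @param onsets_s Annotated SD onsets (s).
#' @param dt_s Matching tolerance (s).
#' @return Tibble (`start_s`, `end_s`, `speed_mm_min`); empty when there is
#'   no true detection.
#' @export
speed_summary <- function(detection, onsets_s, dt_s = 3600) {
  runs <- detection$runs
  if (!nrow(runs)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          speed_mm_min = numeric()))
  }
  is_tp <- vapply(seq_len(nrow(runs)), function(i) {
    any(onsets_s >= runs$start_s[i] - dt_s & onsets_s <= runs$end_s[i] + dt_s)
  }, logical(1))
  runs <- runs[is_tp, ]
  tibble::tibble(start_s = runs$start_s, end_s = runs$end_s,
                 speed_mm_min = runs$mean_speed_mm_min)
}
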