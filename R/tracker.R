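# 8-connected component labelling (binary matrix -> integer labels, 0 = bg)
label_components <- function(bw) {
  lab <- matrix(0L, nrow(bw), ncol(bw))
  cur <- 0L
  idx <- which(bw != 0)
  nr <- nrow(bw)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > ncol(bw)) next
        q <- (cc - 1L) * nr + rr
        if (bw[q] != 0 && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Effective propagation measure of a flow set
#'
#' The magnitude of the mean flow vector inside a bounding box:
#' `sqrt(mean(|V| cos a)^2 + mean(|V| sin a)^2)`. It is 0 when the flows are
#' radially symmetric (a connected component popping up or fading in place)
#' or all zero, and equals the common magnitude when all flows align -
#' for unit-magnitude flows it lies in `[0, 1]` and measures how coherently
#' the component is actually travelling.
#'
#' @param mag Flow magnitudes `|V_i|`.
#' @param ang Flow orientations `a_i` in radians.
#' @return The scalar EPM; `NA` for an empty flow set (such a box is
#'   discarded by the caller).
#' @export
effective_propagation <- function(mag, ang) {
  stopifnot(length(mag) == length(ang))
  if (!length(mag)) return(NA_real_)
  sqrt(mean(mag * cos(ang))^2 + mean(mag * sin(ang))^2)
}

#' Extract orientation bounding boxes from one binary frame
#'
#' 8-connected components of the binary wavefront image become bounding
#' boxes. Flows of a box are the spherical flow vectors at its member
#' pixels. Boxes whose direction-normalized EPM (unit-magnitude flows;
#' zero-magnitude flows enter as zeros, as immobile pixels dilute coherent
#' propagation) falls below `thr2` are non-propagating (pop-up/fade) and are
#' dropped. Surviving boxes are split by the prominent direction(s) of an
#' 8-bin, 45-degree magnitude-weighted orientation histogram of their moving
#' flows: every bin holding at least `prominence` of the maximum bin mass
#' yields an OBBox, so a wavefront travelling near a bin boundary is
#' represented in both straddling bins instead of flickering between them.
#'
#' @param bw Binary frame (matrix).
#' @param vsph List `vx`,`vy` (mm/frame) from [map_to_sphere()].
#' @param thr2 EPM threshold in `[0, 1]` (learnable; default 0.6, the
#'   cross-validated optimum).
#' @param frame Frame index attached to the boxes.
#' @param grid,montage Geometry used for the box centre on the sphere.
#' @param frame_dt_s Frame interval (s), for the mm/min speed.
#' @param prominence Fraction of the maximum histogram mass a bin needs to
#'   count as a prominent direction (default 0.5).
#' @return Tibble with one row per OBBox: `frame`, `bin` (0-7), centre
#'   angles, `speed_mm_min`, `epm`, `n_flows`.
#' @export
make_obboxes <- function(bw, vsph, thr2 = 0.6, frame = 1L,
                         grid = NULL, montage = NULL, frame_dt_s = 30,
                         prominence = 0.5) {
  stopifnot(thr2 >= 0, thr2 <= 1)
  lab <- label_components(bw)
  out <- list()
  for (comp in seq_len(max(lab))) {
    px <- which(lab == comp)
    vx <- vsph$vx[px]
    vy <- vsph$vy[px]
    mag <- sqrt(vx^2 + vy^2)
    ang <- atan2(vy, vx)
    epm <- effective_propagation((mag > 0) * 1, ang)
    if (!is.finite(epm) || epm < thr2) next
    moving <- mag > 0
    if (!any(moving)) next
    bins <- orientation_bin(ang[moving])
    hist8 <- vapply(0:7, function(b) sum(mag[moving][bins == b]),
                    numeric(1))
    top <- which(hist8 >= prominence * max(hist8)) - 1L
    rows <- (px - 1L) %% nrow(bw) + 1L
    cols <- (px - 1L) %/% nrow(bw) + 1L
    ctr <- pixel_to_angles(grid, mean(rows), mean(cols))
    # propagation speed of the component: Eq.-2 form on the physical flow
    # magnitudes (net propagation velocity; incoherent boundary jitter
    # cancels in the vector mean)
    speed <- effective_propagation(mag, ang) * (60 / frame_dt_s)
    for (b in top) {
      member <- which(moving)[bins == b]
      out[[length(out) + 1L]] <- tibble::tibble(
        frame = frame, bin = b,
        phi = ctr[1, 1], theta = ctr[1, 2],
        speed_mm_min = speed,
        epm = epm, n_flows = length(member)
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(frame = integer(), bin = integer(),
                          phi = numeric(), theta = numeric(),
                          speed_mm_min = numeric(), epm = numeric(),
                          n_flows = integer()))
  }
  dplyr::bind_rows(out)
}

# quantize orientations (radians) into 8 bins of 45 deg centred on 0, 45, ...
orientation_bin <- function(ang) {
  as.integer(round(((ang %% (2 * pi)) / (pi / 4))) %% 8)
}

#' Score OBBoxes by spatiotemporal consistency of propagation
#'
#' Boxes propagating outside the physiological speed range (default
#' `[0.5, 8]` mm/min) are removed. For each remaining box, neighbours are
#' boxes with the same orientation bin within `radius_mm` great-circle
#' distance (default 70 mm, covering the coarse inter-electrode spacing)
#' and within `thr3_min` minutes before or after its frame; the
#' spatiotemporal score is the neighbour count. A box whose fraction of
#' frames in that temporal window containing at least one neighbour is
#' below `thr4` lacks temporal consistency and is zeroed.
#'
#' @param boxes OBBox tibble from [make_obboxes()] over all frames.
#' @param montage The montage (head radius).
#' @param radius_mm Spatial neighbourhood radius.
#' @param thr3_min Temporal neighbourhood half-width, minutes (learnable;
#'   default 2).
#' @param thr4 Minimum fraction of contributing frames in `[0, 1]`
#'   (learnable; default 0.69, the cross-validated optimum).
#' @param speed_range Allowed propagation speed, mm/min.
#' @param frame_dt_s Frame interval, seconds.
#' @return The tibble of surviving boxes with a `score` column.
#' @export
score_obboxes <- function(boxes, montage, radius_mm = 70, thr3_min = 2,
                          thr4 = 0.69, speed_range = c(0.5, 8),
                          frame_dt_s = 30) {
  stopifnot(thr4 >= 0, thr4 <= 1, thr3_min > 0)
  boxes <- dplyr::filter(boxes, .data$speed_mm_min >= speed_range[1],
                         .data$speed_mm_min <= speed_range[2])
  n <- nrow(boxes)
  boxes$score <- 0
  if (n == 0) return(boxes)
  half_frames <- round(thr3_min * 60 / frame_dt_s)
  pts <- cbind(boxes$phi, boxes$theta)
  score <- numeric(n)
  for (i in seq_len(n)) {
    cand <- which(boxes$bin == boxes$bin[i] &
                    abs(boxes$frame - boxes$frame[i]) <= half_frames &
                    seq_len(n) != i)
    if (length(cand)) {
      d <- great_circle_mm(montage, pts[rep(i, length(cand)), , drop = FALSE],
                           pts[cand, , drop = FALSE])
      cand <- cand[d <= radius_mm]
    }
    score[i] <- length(cand)
    if (length(cand)) {
      frames_with <- length(unique(boxes$frame[cand]))
      total <- 2 * half_frames + 1
      if (frames_with / total < thr4) score[i] <- 0
    }
  }
  boxes$score <- score
  boxes
}

#' Stitch scored OBBoxes into the binary detection trace
#'
#' Per frame, boxes scoring below 1% of that frame's maximum box score are
#' rejected and the frame score is the sum of the surviving box scores.
#' Frames scoring below 5% of the median nonzero frame score are dropped.
#' The remaining frames are stitched: gaps of at most `stitch_s` seconds
#' (default 2 min) between selected frames are bridged, yielding contiguous
#' detection runs.
#'
#' @param boxes Scored OBBox tibble.
#' @param times Frame times (s) of the full frame grid.
#' @param frame_dt_s Frame interval, seconds.
#' @param stitch_s Stitching window, seconds.
#' @return An `sd_detection` object: tibble `trace` (`time_s`,
#'   `detected`), tibble `runs` (`start_s`, `end_s`, `mean_speed_mm_min`),
#'   and `frame_dt`.
#' @export
stitch_detections <- function(boxes, times, frame_dt_s = 30,
                              stitch_s = 120) {
  nf <- length(times)
  frame_score <- numeric(nf)
  keep <- boxes[0, ]
  if (nrow(boxes)) {
    boxes <- dplyr::filter(boxes, .data$score > 0)
  }
  if (nrow(boxes)) {
    keep <- boxes |>
      dplyr::group_by(.data$frame) |>
      dplyr::filter(.data$score >= 0.01 * max(.data$score)) |>
      dplyr::ungroup()
    fs <- keep |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(score = sum(.data$score), .groups = "drop")
    frame_score[fs$frame] <- fs$score
  }
  nz <- frame_score[frame_score > 0]
  sel <- if (length(nz)) frame_score >= 0.05 * stats::median(nz) &
    frame_score > 0 else rep(FALSE, nf)
  detected <- stitch_gaps(sel, frame_dt_s, stitch_s)
  runs <- run_table(detected, times, frame_dt_s)
  if (nrow(runs)) {
    runs$mean_speed_mm_min <- vapply(seq_len(nrow(runs)), function(i) {
      in_run <- keep$frame %in%
        which(times >= runs$start_s[i] & times < runs$end_s[i])
      if (any(in_run)) mean(keep$speed_mm_min[in_run]) else NA_real_
    }, numeric(1))
  } else {
    runs$mean_speed_mm_min <- numeric(0)
  }
  structure(
    list(trace = tibble::tibble(time_s = times, detected = detected * 1L),
         runs = runs, frame_dt = frame_dt_s, boxes = keep),
    class = "sd_detection"
  )
}

# bridge FALSE gaps of <= stitch_s between TRUE frames
stitch_gaps <- function(sel, frame_dt_s, stitch_s) {
  idx <- which(sel)
  if (length(idx) < 2) return(sel)
  max_gap <- floor(stitch_s / frame_dt_s)
  for (k in seq_len(length(idx) - 1)) {
    if (idx[k + 1] - idx[k] - 1 <= max_gap) sel[idx[k]:idx[k + 1]] <- TRUE
  }
  sel
}

# contiguous TRUE runs -> tibble(start_s, end_s) (end exclusive)
run_table <- function(detected, times, frame_dt_s) {
  r <- rle(detected)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  tibble::tibble(start_s = times[starts[on]],
                 end_s = times[ends[on]] + frame_dt_s)
}

#' @export
print.sd_detection <- function(x, ...) {
  cat(sprintf("<sd_detection> %d frames, %d detection run(s), %.1f min detected\n",
              nrow(x$trace), nrow(x$runs),
              sum(x$trace$detected) * x$frame_dt / 60))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
tidy.sd_detection <- function(x, ...) x$trace

#' Write / read a detection trace as a two-column table
#'
#' @param det An `sd_detection`.
#' @param path File path (TSV with columns `frame_time_s`, `detected`).
#' @export
write_detection <- function(det, path) {
  utils::write.table(
    data.frame(frame_time_s = det$trace$time_s,
               detected = det$trace$detected),
    path, sep = "\t", row.names = FALSE)
  invisible(path)
}
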