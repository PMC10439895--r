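# --- spatial resampling -----------------------------------------------------

# separable Catmull-Rom (bicubic) resampling with edge clamping
cubic_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

cubic_resize_axis <- function(m, n_out) {
  n_in <- nrow(m)
  if (n_out == n_in) return(m)
  scale <- n_in / n_out
  pos <- (seq_len(n_out) - 0.5) * scale + 0.5   # source coordinate (1-based)
  out <- matrix(0, n_out, ncol(m))
  for (i in seq_len(n_out)) {
    base <- floor(pos[i])
    idx <- pmin(n_in, pmax(1L, base + (-1:2)))
    w <- cubic_kernel(pos[i] - (base + (-1:2)))
    w <- w / sum(w)
    out[i, ] <- w %*% m[idx, , drop = FALSE]
  }
  out
}

cubic_resize <- function(img, n_rows_out, n_cols_out) {
  t(cubic_resize_axis(t(cubic_resize_axis(img, n_rows_out)), n_cols_out))
}

#' Choose the spatial subsampling factor for binary wavefront images
#'
#' Picks the smallest integer downscale factor of the pixel grid that brings
#' neighbouring electrodes within 3 pixels of each other (the minimum
#' nearest-neighbour distance between electrode pixels drops below 3) while
#' every projected electrode still maps to its own pixel. Subsampling just
#' far enough - and no further - captures wavefront propagation across
#' electrodes without quantizing away the sub-pixel frame-to-frame motion
#' that calibrates the speed estimates.
#'
#' @param montage,grid Montage and full-resolution grid.
#' @param labels Electrode subset (the ipsilateral set).
#' @return Integer subsampling factor (divides both grid dimensions).
#' @export
choose_subsample_factor <- function(montage, grid, labels) {
  cand <- which(sapply(1:8, function(f)
    grid$n_rows %% f == 0 && grid$n_cols %% f == 0))
  best <- 1L
  for (f in cand) {
    sub <- pixel_grid(grid$n_rows / f, grid$n_cols / f)
    px <- electrode_to_pixel(montage, sub, labels)
    if (anyDuplicated(px[, 1] * 10000L + px[, 2]) > 0) next
    best <- f
    d <- as.matrix(stats::dist(px))
    diag(d) <- Inf
    if (min(d) <= 3) return(f)
  }
  best
}

#' Temporally and spatially subsample binary wavefront images
#'
#' Keeps one binary frame per `frame_dt_s` seconds (default 30 s; the
#' depression signals evolve over minutes, so this loses nothing) and
#' downscales each frame bicubically by `factor` (default: chosen by
#' [choose_subsample_factor()]), re-binarizing at 0.5.
#'
#' @param topo An `sd_topo` at stage `"bw"`.
#' @param montage The montage.
#' @param frame_dt_s Output frame interval, seconds.
#' @param factor Integer downscale factor, or `NULL` to choose
#'   automatically.
#' @return The subsampled `sd_topo` (stage `"bw"`, new `grid`).
#' @export
subsample_frames <- function(topo, montage, frame_dt_s = 30, factor = NULL) {
  stopifnot(inherits(topo, "sd_topo"), topo$stage == "bw")
  step <- max(1L, round(frame_dt_s / topo$frame_dt))
  keep <- seq(1, dim(topo$frames)[3], by = step)
  if (is.null(factor)) {
    factor <- choose_subsample_factor(montage, topo$grid, topo$labels)
  }
  sub <- pixel_grid(topo$grid$n_rows / factor, topo$grid$n_cols / factor)
  arr <- array(0, dim = c(sub$n_rows, sub$n_cols, length(keep)))
  for (k in seq_along(keep)) {
    f <- keep[k]
    if (topo$rejected[f] || sum(topo$frames[, , f]) == 0) next
    img <- if (factor > 1) {
      cubic_resize(topo$frames[, , f], sub$n_rows, sub$n_cols)
    } else {
      topo$frames[, , f]
    }
    arr[, , k] <- (img >= 0.5) * 1
  }
  topo$frames <- arr
  topo$times <- topo$times[keep]
  topo$n_active <- topo$n_active[keep]
  topo$rejected <- topo$rejected[keep]
  topo$grid <- sub
  topo$frame_dt <- topo$frame_dt * step
  topo$electrode_px <- electrode_to_pixel(montage, sub, topo$labels)
  topo
}

# --- optical flow -----------------------------------------------------------

#' Dense Horn-Schunck optical flow between two frames
#'
#' Estimates a dense per-pixel velocity field from the brightness change
#' between two (binary or smoothed) frames using the Horn-Schunck global
#' smoothness formulation. Frames are pre-blurred with a small Gaussian
#' (`preblur_sigma` pixels) so binary edges produce usable gradients. Flow
#' is forced to zero outside the union of the two frames' nonzero support.
#'
#' @param frame1,frame2 Matrices of equal size.
#' @param alpha Smoothness weight (default 1).
#' @param n_iter Fixed iteration count (default 100).
#' @param preblur_sigma Pre-blur width in pixels (default 0.5).
#' @return List `u` (flow along +columns) and `v` (flow along +rows), in
#'   pixels per frame.
#' @export
optical_flow <- function(frame1, frame2, alpha = 1, n_iter = 100,
                         preblur_sigma = 0.5) {
  stopifnot(all(dim(frame1) == dim(frame2)))
  support <- frame1 != 0 | frame2 != 0
  if (!any(support)) {
    z <- matrix(0, nrow(frame1), ncol(frame1))
    return(list(u = z, v = z))
  }
  if (preblur_sigma > 0) {
    frame1 <- gaussian_smooth(frame1, preblur_sigma, preblur_sigma, 0)
    frame2 <- gaussian_smooth(frame2, preblur_sigma, preblur_sigma, 0)
  }
  shift <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    m[pmin(nr, pmax(1L, seq_len(nr) + dr)),
      pmin(nc, pmax(1L, seq_len(nc) + dc)), drop = FALSE]
  }
  # central-difference gradients averaged over the two frames
  gx <- function(m) (shift(m, 0, 1) - shift(m, 0, -1)) / 2
  gy <- function(m) (shift(m, 1, 0) - shift(m, -1, 0)) / 2
  ix <- (gx(frame1) + gx(frame2)) / 2
  iy <- (gy(frame1) + gy(frame2)) / 2
  it <- frame2 - frame1
  u <- v <- matrix(0, nrow(frame1), ncol(frame1))
  denom <- alpha^2 + ix^2 + iy^2
  for (k in seq_len(n_iter)) {
    ubar <- (shift(u, 0, 1) + shift(u, 0, -1) + shift(u, 1, 0) +
               shift(u, -1, 0)) / 6 +
      (shift(u, 1, 1) + shift(u, 1, -1) + shift(u, -1, 1) +
         shift(u, -1, -1)) / 12
    vbar <- (shift(v, 0, 1) + shift(v, 0, -1) + shift(v, 1, 0) +
               shift(v, -1, 0)) / 6 +
      (shift(v, 1, 1) + shift(v, 1, -1) + shift(v, -1, 1) +
         shift(v, -1, -1)) / 12
    common <- (ix * ubar + iy * vbar + it) / denom
    u <- ubar - ix * common
    v <- vbar - iy * common
  }
  u[!support] <- 0
  v[!support] <- 0
  list(u = u, v = v)
}

#' Map 2D pixel flow onto the spherical scalp
#'
#' Converts a per-pixel 2D flow (pixels/frame on the unrolled cylindrical
#' map) into physical scalp velocities (mm/frame): the azimuthal component
#' is scaled by `r * dphi * cos(theta)` (meridians converge toward the
#' vertex) and the polar component by `r * dtheta`, independent of theta.
#' With 30-s frames, speeds in mm/min are `2 |V|`.
#'
#' @param flow List `u`,`v` from [optical_flow()] (v positive = downward on
#'   the image = decreasing theta).
#' @param grid The (subsampled) pixel grid.
#' @param montage The montage (head radius).
#' @return List `vx`, `vy` in mm/frame (`vy` positive toward the vertex).
#' @export
map_to_sphere <- function(flow, grid, montage) {
  r <- montage$head_radius_mm
  costh <- cos(grid_row_theta(grid))
  vx <- r * grid$dphi * flow$u * costh   # recycled by row
  vy <- r * grid$dtheta * (-flow$v)      # +v is downward = -theta
  list(vx = vx, vy = vy)
}
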