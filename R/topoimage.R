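#' Project depression values onto sparse scalp images
#'
#' For each frame of a rectified depression series, the values of the
#' participating (valid) ipsilateral electrodes are written to their grid
#' pixels and every other pixel receives the median of those electrode
#' values, producing the sparse scalp image that the interpolation stage
#' smooths.
#'
#' @param dep An `sd_series` of kind `"depression"`.
#' @param montage An [montage_1020()] object.
#' @param grid An [pixel_grid()] object.
#' @param labels Electrode subset to project (default: the ipsilateral set
#'   implied by `dhc_side`).
#' @param dhc_side DHC side used when `labels` is `NULL`.
#' @return An `sd_topo` object: 3D array `frames` (rows x cols x time),
#'   `times`, `n_active`, `rejected`, `grid`, `stage = "sparse"`.
#' @export
project_frames <- function(dep, montage, grid, dhc_side = NULL,
                           labels = NULL) {
  stopifnot(inherits(dep, "sd_series"), inherits(grid, "sd_grid"))
  if (is.null(labels)) {
    labels <- ipsilateral_subset(montage, dhc_side)
  }
  labels <- intersect(labels, dep$labels)
  px <- electrode_to_pixel(montage, grid, labels)
  chan <- match(labels, dep$labels)
  nf <- ncol(dep$values)
  arr <- array(0, dim = c(grid$n_rows, grid$n_cols, nf))
  n_active <- integer(nf)
  for (f in seq_len(nf)) {
    act <- which(dep$valid[chan, f])
    n_active[f] <- length(act)
    if (!length(act)) next
    v <- dep$values[chan[act], f]
    img <- matrix(stats::median(v), grid$n_rows, grid$n_cols)
    img[cbind(px[act, 1], px[act, 2])] <- v
    arr[, , f] <- img
  }
  structure(
    list(frames = arr, times = dep$times, n_active = n_active,
         rejected = rep(FALSE, nf), grid = grid,
         frame_dt = dep$frame_dt, electrode_px = px,
         labels = labels, stage = "sparse"),
    class = "sd_topo"
  )
}

#' @export
print.sd_topo <- function(x, ...) {
  cat(sprintf("<sd_topo:%s> %d x %d px, %d frames, dt = %g s\n", x$stage,
              x$grid$n_rows, x$grid$n_cols, dim(x$frames)[3], x$frame_dt))
  invisible(x)
}

# separable Gaussian convolution with constant padding (pad value per image)
gaussian_smooth <- function(img, sigma_row, sigma_col, pad_value) {
  k <- function(sigma) {
    hw <- max(1L, ceiling(3 * sigma))
    g <- exp(-((-hw:hw)^2) / (2 * sigma^2))
    g / sum(g)
  }
  conv_rows <- function(m, g) {
    hw <- (length(g) - 1L) %/% 2L
    padded <- rbind(matrix(pad_value, hw, ncol(m)), m,
                    matrix(pad_value, hw, ncol(m)))
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(g)) {
      out <- out + g[i] * padded[i:(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  img <- conv_rows(img, k(sigma_row))
  t(conv_rows(t(img), k(sigma_col)))
}

#' Interpolate sparse scalp images with a Gaussian kernel
#'
#' Smooths each sparse frame with a 2D Gaussian of physical width
#' `sigma_mm` (default 26.2 mm, chosen large because the mean inter-electrode
#' distance of the 10-20 montage is ~54 mm). The width is converted to
#' pixels per axis using the equatorial pixel size (`r dphi`, `r dtheta`);
#' the cos(theta) metric distortion is ignored because smoothing operates on
#' the unrolled 2D plane. Borders are padded with the frame's electrode
#' median before convolution.
#'
#' @param topo An `sd_topo` at stage `"sparse"`.
#' @param montage The montage (for the head radius).
#' @param sigma_mm Gaussian standard deviation on the scalp, millimetres.
#' @return The `sd_topo` at stage `"smooth"`.
#' @export
interpolate_frames <- function(topo, montage, sigma_mm = 26.2) {
  stopifnot(inherits(topo, "sd_topo"), topo$stage == "sparse")
  r <- montage$head_radius_mm
  s_col <- sigma_mm / (r * topo$grid$dphi)
  s_row <- sigma_mm / (r * topo$grid$dtheta)
  for (f in seq_len(dim(topo$frames)[3])) {
    if (topo$n_active[f] == 0) next
    img <- topo$frames[, , f]
    pad <- stats::median(img[cbind(topo$electrode_px[, 1],
                                   topo$electrode_px[, 2])])
    topo$frames[, , f] <- gaussian_smooth(img, s_row, s_col, pad)
  }
  topo$stage <- "smooth"
  topo
}

#' Threshold smooth scalp images into binary wavefront images
#'
#' Three-stage rule per frame: (i) pixels at or below
#' `M + Thr1 (H - M)` are zeroed, where `M` and `H` are the frame's median
#' and maximum pixel values; (ii) frames with fewer than `min_active`
#' participating electrodes (of the 11 ipsilateral) are rejected outright;
#' (iii) surviving pixels are set to 1, and a frame in which more than half
#' of the grid pixels are set is rejected - an SD depression cannot cover
#' more than half the cortical surface. Ties at exactly 50% keep the frame.
#'
#' @param topo An `sd_topo` at stage `"smooth"`.
#' @param thr1 Depression-level threshold in `[0, 1]` (learnable; default
#'   0.3, the cross-validated optimum).
#' @param min_active Minimum participating electrodes (default 5).
#' @return The `sd_topo` at stage `"bw"` with binary frames and updated
#'   `rejected` flags.
#' @export
threshold_frames <- function(topo, thr1 = 0.3, min_active = 5) {
  stopifnot(inherits(topo, "sd_topo"), topo$stage == "smooth",
            thr1 >= 0, thr1 <= 1)
  n_px <- topo$grid$n_rows * topo$grid$n_cols
  for (f in seq_len(dim(topo$frames)[3])) {
    img <- topo$frames[, , f]
    if (topo$n_active[f] < min_active) {
      topo$frames[, , f] <- 0
      topo$rejected[f] <- TRUE
      next
    }
    m <- stats::median(img)
    h <- max(img)
    bw <- (img > m + thr1 * (h - m)) * 1
    if (sum(bw) > n_px / 2) {
      bw[] <- 0
      topo$rejected[f] <- TRUE
    }
    topo$frames[, , f] <- bw
  }
  topo$stage <- "bw"
  topo
}
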