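#' Electrode montage on a spherical head model
#'
#' Builds a 10-20 scalp electrode montage on a sphere of radius
#' `head_radius_mm`. Coordinates use azimuth `phi` (radians, 0 = right
#' preauricular axis, positive toward the nasion) and polar angle `theta`
#' (radians, `pi/2` at the vertex, 0 on the equator through nasion, inion and
#' the preauricular points). The default coordinate table is a standard
#' idealized 10-20 layout shipped with the package
#' (`inst/extdata/montage_1020.tsv`) and can be replaced by any table with
#' columns `label`, `az_deg`, `polar_deg`; the geometry enters the algorithm
#' only through great-circle distances and the pixel projection.
#'
#' @param head_radius_mm Scalp sphere radius in millimetres (default 75, an
#'   average adult head radius).
#' @param coords Optional replacement coordinate data frame with columns
#'   `label`, `az_deg`, `polar_deg`.
#' @return An object of class `sd_montage`: a list with `labels`, `phi`,
#'   `theta` (named radian vectors) and `head_radius_mm`.
#' @examples
#' m <- montage_1020()
#' ipsilateral_subset(m, "right")
#' @export
montage_1020 <- function(head_radius_mm = 75, coords = NULL) {
  if (is.null(coords)) {
    path <- system.file("extdata", "montage_1020.tsv", package = "sdwave")
    coords <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "az_deg", "polar_deg") %in% names(coords)),
            head_radius_mm > 0)
  phi <- wrap_angle(coords$az_deg * pi / 180)
  theta <- coords$polar_deg * pi / 180
  if (any(theta < -1e-9 | theta > pi / 2 + 1e-9)) {
    stop("polar angles must lie in [0, pi/2] (pi/2 = vertex)")
  }
  names(phi) <- names(theta) <- coords$label
  structure(
    list(labels = coords$label, phi = phi, theta = theta,
         head_radius_mm = head_radius_mm),
    class = "sd_montage"
  )
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi + 1e-12] <- pi
  a
}

#' @export
print.sd_montage <- function(x, ...) {
  cat("<sd_montage> ", length(x$labels), " electrodes, r = ",
      x$head_radius_mm, " mm\n", sep = "")
  invisible(x)
}

#' Ipsilateral electrode subset for a hemicraniectomy side
#'
#' Returns the 8 lateral 10-20 electrodes over the hemisphere that underwent
#' decompressive hemicraniectomy (DHC) plus the three midline electrodes
#' (Fz, Cz, Pz), which are sensitive to sources on either side - 11 labels in
#' a fixed anterior-to-posterior order.
#'
#' @param montage An [montage_1020()] object.
#' @param dhc_side `"left"` or `"right"`.
#' @return Character vector of 11 electrode labels.
#' @export
ipsilateral_subset <- function(montage, dhc_side) {
  stopifnot(inherits(montage, "sd_montage"))
  dhc_side <- match.arg(dhc_side, c("left", "right"))
  lateral <- switch(dhc_side,
    right = c("Fp2", "F8", "F4", "T8", "C4", "P8", "P4", "O2"),
    left  = c("Fp1", "F7", "F3", "T7", "C3", "P7", "P3", "O1"))
  labels <- c(lateral, "Fz", "Cz", "Pz")
  missing <- setdiff(labels, montage$labels)
  if (length(missing)) {
    stop("montage is missing required electrodes: ",
         paste(missing, collapse = ", "))
  }
  labels
}

#' Great-circle distance between electrodes or scalp points
#'
#' @param montage An [montage_1020()] object.
#' @param from,to Electrode labels, or 2-column matrices of `(phi, theta)`
#'   in radians.
#' @return Distance(s) along the scalp sphere, in millimetres.
#' @export
great_circle_mm <- function(montage, from, to) {
  ang <- function(p) {
    if (is.character(p)) {
      cbind(montage$phi[p], montage$theta[p])
    } else {
      matrix(p, ncol = 2)
    }
  }
  a <- ang(from); b <- ang(to)
  ca <- cos(a[, 2]) * cos(a[, 1]); sa <- cos(a[, 2]) * sin(a[, 1])
  cb <- cos(b[, 2]) * cos(b[, 1]); sb <- cos(b[, 2]) * sin(b[, 1])
  dot <- ca * cb + sa * sb + sin(a[, 2]) * sin(b[, 2])
  montage$head_radius_mm * acos(pmin(1, pmax(-1, dot)))
}

#' Cylindrical pixel grid over the upper hemisphere
#'
#' The scalp sphere is unrolled onto a 2D grid: columns sample azimuth
#' `phi in [-pi, pi)` and rows sample polar angle `theta in [0, pi/2]`, with
#' row 1 at the vertex (`theta = pi/2`) and the bottom row on the equator.
#' The default 64 x 32 resolution leaves at least 3 pixels between
#' neighbouring 10-20 electrodes before any spatial subsampling.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @return An `sd_grid` object with per-pixel angular resolutions `dphi`,
#'   `dtheta` (radians).
#' @export
pixel_grid <- function(n_rows = 32, n_cols = 64) {
  stopifnot(n_rows >= 2, n_cols >= 2)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         dphi = 2 * pi / n_cols, dtheta = (pi / 2) / n_rows),
    class = "sd_grid"
  )
}

#' @export
print.sd_grid <- function(x, ...) {
  cat("<sd_grid> ", x$n_rows, " x ", x$n_cols, " (rows x cols)\n", sep = "")
  invisible(x)
}

#' Map scalp angles to grid pixels and back
#'
#' `angles_to_pixel()` bins `(phi, theta)` into 1-based `(row, col)` indices;
#' `pixel_to_angles()` returns the cell-centre angles, so the round trip is
#' exact up to one pixel.
#'
#' @param grid An [pixel_grid()] object.
#' @param phi,theta Angles in radians.
#' @param row,col 1-based pixel indices.
#' @return A 2-column matrix (`row`,`col` or `phi`,`theta`).
#' @export
angles_to_pixel <- function(grid, phi, theta) {
  phi <- wrap_angle(phi)
  col <- pmin(grid$n_cols, pmax(1L, floor((phi + pi) / grid$dphi) + 1L))
  row <- pmin(grid$n_rows, pmax(1L, floor((pi / 2 - theta) / grid$dtheta) + 1L))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname angles_to_pixel
#' @export
pixel_to_angles <- function(grid, row, col) {
  cbind(phi = -pi + (col - 0.5) * grid$dphi,
        theta = pi / 2 - (row - 0.5) * grid$dtheta)
}

#' @rdname angles_to_pixel
#' @param montage An [montage_1020()] object.
#' @param label Electrode label(s) present in the montage.
#' @export
electrode_to_pixel <- function(montage, grid, label) {
  if (!all(label %in% montage$labels)) {
    stop("unknown electrode label(s): ",
         paste(setdiff(label, montage$labels), collapse = ", "))
  }
  angles_to_pixel(grid, montage$phi[label], montage$theta[label])
}

# node-centred polar angle per row: row 1 sits exactly at the vertex
# (theta = pi/2), so azimuthal physical velocity vanishes there (the arc
# length r dphi cos(theta) is zero at the pole)
grid_row_theta <- function(grid) {
  pi / 2 - (seq_len(grid$n_rows) - 1) * grid$dtheta
}
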