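#' Algebraic least-squares circle fit
#'
#' Fits a circle to `n >= 3` points by the Kåsa method: minimize
#' `sum((x^2 + y^2 + D x + E y + F)^2)` over the linear parameters
#' `(D, E, F)`. For exactly concyclic points the fit is exact; the beam
#' centre of a scattering pattern is found by fitting points marked around
#' the circumference of a diffraction ring (seven points is the customary
#' default).
#'
#' @param points numeric matrix (or two-column data frame) of `(row, col)`
#'   pixel coordinates, one point per row.
#' @return An object of class `circle_fit`: list with `centre` (named
#'   `(row, col)`), `radius` (pixels) and `rms_residual` (RMS radial
#'   distance of the points from the fitted circle, pixels).
#' @export
fit_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    saxs_geometry_error("circle fit needs at least 3 points")
  y <- points[, 1]  # row
  x <- points[, 2]  # col
  A <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  qrA <- qr(A)
  if (qrA$rank < 3L)
    saxs_geometry_error("points are collinear or degenerate: no unique circle")
  sol <- qr.coef(qrA, rhs)       # (D, E, F)
  cx <- -sol[1] / 2; cy <- -sol[2] / 2
  r2 <- cx^2 + cy^2 - sol[3]
  if (!is.finite(r2) || r2 <= 0)
    saxs_geometry_error("degenerate circle fit (non-positive radius)")
  radius <- sqrt(r2)
  resid <- sqrt((x - cx)^2 + (y - cy)^2) - radius
  structure(list(centre = c(row = unname(cy), col = unname(cx)),
                 radius = unname(radius),
                 rms_residual = sqrt(mean(resid^2))),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: centre (row %.4f, col %.4f), radius %.4f px, RMS residual %.3g px\n",
              x$centre["row"], x$centre["col"], x$radius, x$rms_residual))
  invisible(x)
}

#' Radius and azimuth grids about a centre
#'
#' For every pixel of a `(rows, cols)` grid, the Euclidean distance to the
#' centre (pixels) and the azimuth in degrees. Azimuth convention: 0 deg
#' along the +col axis, increasing counter-clockwise in standard image
#' display (row increasing downward), range `[0, 360)`. A pixel one row
#' above the centre therefore sits at 90 deg.
#'
#' @param shape integer `(rows, cols)`.
#' @param centre numeric `(row, col)`, 1-based.
#' @return list with matrices `radius` and `azimuth_deg`.
#' @export
radial_coordinate <- function(shape, centre) {
  if (centre[1] < 1 - 0.5 || centre[1] > shape[1] + 0.5 ||
      centre[2] < 1 - 0.5 || centre[2] > shape[2] + 0.5)
    saxs_validation_error("centre lies outside the pattern bounds")
  dr <- matrix(seq_len(shape[1]) - centre[1], shape[1], shape[2])
  dc <- matrix(seq_len(shape[2]) - centre[2], shape[1], shape[2], byrow = TRUE)
  radius <- sqrt(dr^2 + dc^2)
  azimuth <- (atan2(-dr, dc) * 180 / pi) %% 360
  list(radius = radius, azimuth_deg = azimuth)
}

#' Pixel-to-d-spacing calibration from one calibrant reflection
#'
#' A single reflection of known d-spacing (for example the 67 nm collagen
#' first-order meridional peak of hydrated rat-tail tendon) at a measured
#' radial pixel position fixes the linear small-angle mapping between pixel
#' radius and scattering-vector magnitude, `K(R) = k_per_pixel * R` with
#' `K = 2*pi/d`.
#'
#' @param r_cal radial pixel position of the calibrant peak (> 0).
#' @param d_cal assigned d-spacing of that reflection in nm (> 0).
#' @return Object of class `saxs_calibration`: list with `r_cal`, `d_cal`
#'   and `k_per_pixel` (nm^-1 per pixel).
#' @export
make_calibration <- function(r_cal, d_cal) {
  if (!is.finite(r_cal) || r_cal <= 0 || !is.finite(d_cal) || d_cal <= 0)
    saxs_validation_error("r_cal and d_cal must be positive")
  structure(list(r_cal = r_cal, d_cal = d_cal,
                 k_per_pixel = (2 * pi / d_cal) / r_cal),
            class = "saxs_calibration")
}

#' @export
print.saxs_calibration <- function(x, ...) {
  cat(sprintf("Calibration: %.4g nm at %.4g px  (K = %.6g nm^-1 per pixel)\n",
              x$d_cal, x$r_cal, x$k_per_pixel))
  invisible(x)
}

#' Scattering-vector magnitude at a pixel radius
#'
#' @param cal a [make_calibration()] object.
#' @param r_px radial position(s) in pixels.
#' @return `K` in nm^-1.
#' @export
k_from_pixel <- function(cal, r_px) cal$k_per_pixel * r_px

#' Calibrated d-spacing of a peak
#'
#' Converts a peak's radial pixel position into a real-space periodicity
#' using the small-angle linear approximation. For a meridional reflection
#' of order `n` this is the axial D-period; for the first-order equatorial
#' interference peak it is the Bragg interfibrillar spacing.
#'
#' @param cal a [make_calibration()] object.
#' @param r_peak radial peak position in pixels (> 0).
#' @param order reflection order (integer >= 1).
#' @return spacing in nm: `order * d_cal * r_cal / r_peak`.
#' @export
spacing_from_pixel <- function(cal, r_peak, order = 1L) {
  if (any(!is.finite(r_peak)) || any(r_peak <= 0))
    saxs_validation_error("r_peak must be positive")
  if (order < 1) saxs_validation_error("order must be >= 1")
  order * cal$d_cal * cal$r_cal / r_peak
}

#' Inverse of [spacing_from_pixel()]
#'
#' @param cal a [make_calibration()] object.
#' @param d_nm spacing in nm (> 0).
#' @param order reflection order.
#' @return radial pixel position at which a reflection of that spacing and
#'   order appears.
#' @export
pixel_from_spacing <- function(cal, d_nm, order = 1L) {
  if (any(!is.finite(d_nm)) || any(d_nm <= 0))
    saxs_validation_error("d_nm must be positive")
  order * cal$d_cal * cal$r_cal / d_nm
}
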