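#' Zero-phase low-pass filter for a circular signal
#'
#' Fourier-domain truncation of a uniformly sampled 360-degree-periodic
#' signal: harmonics `0..keep_harmonics` are retained, all higher ones
#' zeroed. The filter is exactly zero-phase, preserves the circular mean,
#' and is an idempotent projection (applying it twice equals once).
#'
#' @param values numeric vector sampled uniformly around the circle.
#' @param keep_harmonics highest harmonic retained (>= 0).
#' @return filtered real vector, same length.
#' @export
zero_phase_lowpass <- function(values, keep_harmonics = 12) {
  if (!is.numeric(keep_harmonics) || keep_harmonics < 0)
    saxs_validation_error("keep_harmonics must be >= 0")
  n <- length(values)
  if (anyNA(values))
    saxs_validation_error("low-pass filter requires a gap-free signal")
  F <- stats::fft(values)
  harm <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))
  F[harm > keep_harmonics] <- 0
  Re(stats::fft(F, inverse = TRUE)) / n
}

#' Preferentially aligned collagen versus azimuth
#'
#' Radially integrates the background-subtracted intensity over the annulus
#' of a peak of interest, per azimuth bin, then subtracts the azimuthal
#' minimum (the isotropic level). What remains — the "aligned scatter" —
#' is proportional to the relative number of collagen fibrils
#' preferentially oriented with scattering at each azimuth. The power-law
#' background is evaluated per pixel at its radius before integration.
#'
#' Note the plotted azimuth is the SCATTER azimuth; equatorial scatter is
#' perpendicular to the fibril axis, so the fibril-orientation plot is the
#' same curve rotated by 90 degrees (`rotate90` in [write_polar_plot()]).
#'
#' @param p preprocessed [saxs_pattern()].
#' @param centre numeric `(row, col)`.
#' @param r_inner,r_outer annulus limits (pixels) bracketing the peak.
#' @param bg a [fit_power_law()] background, or `NULL` for none.
#' @param bin_deg azimuthal bin width (degrees).
#' @param keep_harmonics cutoff of the zero-phase smoothing filter.
#' @return Object of class `orientation_result`: list with `azimuth_deg`,
#'   `total` (background-subtracted azimuthal profile),
#'   `isotropic_level`, `aligned` (total minus isotropic level) and
#'   `smoothed_aligned`.
#' @export
aligned_scatter <- function(p, centre, r_inner, r_outer, bg = NULL,
                            bin_deg = 1, keep_harmonics = 12) {
  stopifnot(inherits(p, "saxs_pattern"))
  if (!is.null(bg)) {
    stopifnot(inherits(bg, "powerlaw_fit"))
    coords <- radial_coordinate(p$shape, centre)
    sub <- p$intensity - predict(bg, pmax(coords$radius, .Machine$double.eps))
    p <- saxs_pattern(sub, valid = p$valid, source = p$source)
  }
  prof <- integrate_azimuthal(p, centre, r_inner, r_outer, bin_deg)
  total <- prof$intensity
  if (anyNA(total)) {
    # interpolate empty bins circularly so the minimum and the filter are
    # defined on the full circle
    total <- interp_ring(prof$azimuth_deg, total)
    if (anyNA(total))
      saxs_empty_data_error("no valid pixels in orientation annulus")
  }
  iso <- min(total)
  aligned <- total - iso
  structure(list(azimuth_deg = prof$azimuth_deg, total = total,
                 isotropic_level = iso, aligned = aligned,
                 smoothed_aligned = zero_phase_lowpass(aligned, keep_harmonics)),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  pk <- x$azimuth_deg[which.max(x$smoothed_aligned)]
  cat(sprintf("Orientation profile: %d bins, isotropic level %.6g, max aligned %.6g at %g deg\n",
              length(x$azimuth_deg), x$isotropic_level, max(x$aligned), pk))
  invisible(x)
}

#' Write the orientation polar plot (and companion CSV)
#'
#' Polar vector plot of the aligned scatter: the length of the curve from
#' the plot centre in any direction is proportional to the relative amount
#' of preferentially oriented collagen scattering at that azimuth. The
#' plotted data are written unchanged to a two-column CSV next to the
#' image (no plot-only transforms).
#'
#' @param result an [aligned_scatter()] result.
#' @param path output image path (`.png` or `.tif`).
#' @param rotate90 rotate the curve by 90 degrees so that it shows fibril
#'   orientation rather than scatter orientation.
#' @param smoothed plot the low-pass-smoothed curve (default) or the raw
#'   aligned profile.
#' @param csv_path companion CSV path; default replaces the image
#'   extension with `.csv`.
#' @return `path`, invisibly.
#' @export
write_polar_plot <- function(result, path, rotate90 = FALSE, smoothed = TRUE,
                             csv_path = NULL) {
  stopifnot(inherits(result, "orientation_result"))
  v <- if (smoothed) result$smoothed_aligned else result$aligned
  v <- pmax(v, 0)
  az <- result$azimuth_deg + if (rotate90) 90 else 0
  if (is.null(csv_path))
    csv_path <- paste0(tools::file_path_sans_ext(path), ".csv")
  write_orientation_profile(result$azimuth_deg,
                            if (smoothed) result$smoothed_aligned else result$aligned,
                            csv_path)
  theta <- az * pi / 180
  xx <- c(v * cos(theta), v[1] * cos(theta[1]))
  yy <- c(v * sin(theta), v[1] * sin(theta[1]))
  lim <- max(v, .Machine$double.eps) * 1.05
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 3, 1), pty = "s")
  graphics::plot(xx, yy, type = "l", lwd = 2, col = "steelblue4",
                 xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "", ylab = "",
                 main = sprintf("Aligned collagen %s orientation",
                                if (rotate90) "fibril" else "scatter"))
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(path)
}
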