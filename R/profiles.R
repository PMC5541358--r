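# NaN-aware reduction of the 2D pattern to 1D profiles. Bins take the MEAN
# of their valid pixels, not the sum: with detector gaps and masks a sum
# depends on the arbitrary number of surviving pixels, a mean does not.
# Sums are recoverable as intensity * n_valid.

new_profile <- function(x, intensity, n_valid, xname, class) {
  df <- data.frame(x, intensity = intensity, n_valid = n_valid)
  names(df)[1] <- xname
  structure(df, class = c(class, "data.frame"))
}

#' Azimuthally integrated radial profile
#'
#' Bin `b` (bin centres spaced `bin_px` pixels) collects the valid pixels
#' whose radius rounds to that bin; the profile intensity is their
#' arithmetic mean. Bins with no valid pixel have `NA` intensity.
#'
#' @param p a [saxs_pattern()].
#' @param centre numeric `(row, col)`.
#' @param r_min,r_max radial range (pixels) to include.
#' @param bin_px radial bin width in pixels.
#' @return A `radial_profile` data frame with columns `radius_px`,
#'   `intensity`, `n_valid`.
#' @export
integrate_radial <- function(p, centre, r_min = 0, r_max = Inf, bin_px = 1) {
  stopifnot(inherits(p, "saxs_pattern"))
  if (!(r_min < r_max)) saxs_validation_error("r_min must be < r_max")
  coords <- radial_coordinate(p$shape, centre)
  sel <- p$valid & coords$radius >= r_min & coords$radius <= r_max
  if (!any(sel)) saxs_empty_data_error("no valid pixels in radial range")
  bin <- round(coords$radius[sel] / bin_px)
  v <- p$intensity[sel]
  bins <- seq(min(bin), max(bin))
  idx <- bin - bins[1] + 1L
  sums <- unname(rowsum(v, idx, reorder = TRUE))
  present <- sort(unique(idx))
  counts <- tabulate(idx, nbins = length(bins))
  intensity <- rep(NA_real_, length(bins))
  intensity[present] <- sums / counts[present]
  new_profile(bins * bin_px, intensity, counts, "radius_px", "radial_profile")
}

#' Radially integrated azimuthal profile
#'
#' Bin centres cover `[0, 360)` in steps of `bin_deg`; bin `phi` collects
#' the valid pixels of the annulus `[r_inner, r_outer]` whose azimuth lies
#' in `[phi - bin/2, phi + bin/2)`, and takes their mean intensity.
#'
#' @param p a [saxs_pattern()].
#' @param centre numeric `(row, col)`.
#' @param r_inner,r_outer annulus limits in pixels.
#' @param bin_deg azimuthal bin width in degrees (must divide 360).
#' @return An `azimuthal_profile` data frame with columns `azimuth_deg`,
#'   `intensity`, `n_valid`.
#' @export
integrate_azimuthal <- function(p, centre, r_inner, r_outer, bin_deg = 1) {
  stopifnot(inherits(p, "saxs_pattern"))
  if (!(r_inner >= 0 && r_inner < r_outer))
    saxs_validation_error("annulus requires 0 <= r_inner < r_outer")
  nbin <- round(360 / bin_deg)
  if (abs(nbin * bin_deg - 360) > 1e-9)
    saxs_validation_error("bin_deg must divide 360")
  coords <- radial_coordinate(p$shape, centre)
  sel <- p$valid & coords$radius >= r_inner & coords$radius <= r_outer
  if (!any(sel)) saxs_empty_data_error("no valid pixels in annulus")
  az <- coords$azimuth_deg[sel]
  idx <- (floor(az / bin_deg + 0.5) %% nbin) + 1L
  v <- p$intensity[sel]
  agg <- rowsum(v, idx)
  counts <- tabulate(idx, nbins = nbin)
  intensity <- rep(NA_real_, nbin)
  intensity[as.integer(rownames(agg))] <- agg[, 1] / counts[counts > 0]
  new_profile(seq_len(nbin) * bin_deg - bin_deg, intensity, counts,
              "azimuth_deg", "azimuthal_profile")
}
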