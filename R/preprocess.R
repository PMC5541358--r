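# Pattern corrections applied, in pipeline order: negative-offset shift,
# background-image subtraction, threshold masking, symmetry gap filling.

#' Shift negative intensities to zero
#'
#' Detector calibration can leave raw patterns with negative counts. If the
#' minimum over valid pixels is negative, that minimum is subtracted from
#' the whole matrix (new minimum exactly 0); otherwise the pattern is
#' returned unchanged. Pairwise intensity differences are preserved.
#'
#' @param p a [saxs_pattern()].
#' @return corrected [saxs_pattern()].
#' @export
correct_negative <- function(p) {
  stopifnot(inherits(p, "saxs_pattern"))
  if (!any(p$valid)) return(p)
  mn <- min(p$intensity[p$valid])
  if (mn >= 0) return(p)
  p$intensity <- p$intensity - mn
  p
}

#' Subtract a background image
#'
#' Removes background scatter (specimen cell, beamstop flare) recorded in a
#' separate exposure: `intensity = p - scale * bg`, with the validity mask
#' the AND of both masks. With no background image the pipeline uses a zero
#' background (identity).
#'
#' @param p a [saxs_pattern()].
#' @param bg background [saxs_pattern()] of identical shape, or `NULL`.
#' @param scale scale factor applied to `bg`.
#' @return background-subtracted [saxs_pattern()].
#' @export
subtract_background_image <- function(p, bg = NULL, scale = 1) {
  stopifnot(inherits(p, "saxs_pattern"))
  if (is.null(bg)) return(p)
  stopifnot(inherits(bg, "saxs_pattern"))
  if (!identical(p$shape, bg$shape))
    saxs_validation_error(sprintf(
      "background shape (%d x %d) does not match pattern (%d x %d)",
      bg$shape[1], bg$shape[2], p$shape[1], p$shape[2]))
  saxs_pattern(p$intensity - scale * bg$intensity,
               valid = p$valid & bg$valid, source = p$source)
}

#' Intensity/radial mask specification
#'
#' Lower/upper intensity thresholds (LL/UL) mark outlier pixels — beamstop
#' flare, hot pixels — as missing; the radial limits Ri/Rio bound the
#' annulus used in azimuthal integration but do not invalidate pixels.
#'
#' @param ll,ul intensity thresholds, `ll < ul`.
#' @param ri,rio radial limits in pixels, `0 <= ri < rio`.
#' @return object of class `mask_spec`.
#' @export
mask_spec <- function(ll = -Inf, ul = Inf, ri = 0, rio = Inf) {
  if (!(ll < ul)) saxs_validation_error("mask requires LL < UL")
  if (!(ri >= 0 && ri < rio)) saxs_validation_error("mask requires 0 <= Ri < Rio")
  structure(list(ll = ll, ul = ul, ri = ri, rio = rio), class = "mask_spec")
}

#' Mark out-of-threshold pixels as missing
#'
#' Pixels with intensity below `LL` or above `UL` become invalid (missing
#' data). Surviving pixel values are never altered. The radial limits of
#' `spec` are attached to the returned pattern as the default integration
#' annulus but leave pixel validity untouched.
#'
#' @param p a [saxs_pattern()].
#' @param spec a [mask_spec()].
#' @return masked [saxs_pattern()] with an `annulus` element `c(ri, rio)`.
#' @export
apply_mask <- function(p, spec) {
  stopifnot(inherits(p, "saxs_pattern"), inherits(spec, "mask_spec"))
  drop <- p$valid & (p$intensity < spec$ll | p$intensity > spec$ul)
  out <- saxs_pattern(p$intensity, valid = p$valid & !drop, source = p$source)
  out$annulus <- c(spec$ri, spec$rio)
  out
}

# Circular linear interpolation of NA values on one ring, ordered by azimuth.
interp_ring <- function(az, values) {
  miss <- is.na(values)
  if (!any(miss) || all(miss)) return(values)
  ord <- order(az)
  az_s <- az[ord]; v_s <- values[ord]
  good <- which(!is.na(v_s))
  # wrap the last valid point below the first and the first above the last
  ga <- c(az_s[good[length(good)]] - 360, az_s[good], az_s[good[1]] + 360)
  gv <- c(v_s[good[length(good)]], v_s[good], v_s[good[1]])
  bad <- which(is.na(v_s))
  v_s[bad] <- stats::approx(ga, gv, xout = az_s[bad], ties = "ordered")$y
  values[ord] <- v_s
  values
}

#' Recover missing data by order-2 symmetry and circumferential interpolation
#'
#' A fibre-diffraction pattern from collagenous tissue has (neglecting
#' out-of-plane effects) rotational symmetry of order 2 about the scattering
#' centre. Pass 1 populates each invalid pixel from its point reflection
#' through the centre (nearest-pixel rounding of the rotated coordinate)
#' when that partner is valid. Pass 2 fills the remainder by linear
#' interpolation in azimuth between the nearest valid pixels on the same
#' integer-radius ring, wrapping at 360 deg. Rings with no valid pixel at
#' all are left invalid with a warning.
#'
#' @param p a [saxs_pattern()].
#' @param centre numeric `(row, col)` symmetry centre.
#' @param r_outer fill only rings with rounded radius `<= r_outer`
#'   (default: the whole pattern).
#' @return filled [saxs_pattern()].
#' @export
fill_gaps <- function(p, centre, r_outer = Inf) {
  stopifnot(inherits(p, "saxs_pattern"))
  intens <- p$intensity
  nr <- p$shape[1]; nc <- p$shape[2]
  bad <- which(!p$valid)
  if (length(bad) == 0L) return(p)

  # pass 1: point reflection through the centre
  br <- ((bad - 1L) %% nr) + 1L
  bc <- ((bad - 1L) %/% nr) + 1L
  pr <- as.integer(round(2 * centre[1] - br))
  pc <- as.integer(round(2 * centre[2] - bc))
  inside <- pr >= 1L & pr <= nr & pc >= 1L & pc <= nc
  partner <- (pc - 1L) * nr + pr
  usable <- inside
  usable[inside] <- p$valid[partner[inside]]
  intens[bad[usable]] <- p$intensity[partner[usable]]

  # pass 2: circumferential interpolation on integer-radius rings
  still <- is.na(intens)
  if (any(still)) {
    coords <- radial_coordinate(p$shape, centre)
    rr <- round(coords$radius)
    for (ring in unique(rr[still])) {
      if (ring > r_outer) next
      on_ring <- which(rr == ring)
      v <- intens[on_ring]
      if (all(is.na(v))) {
        warning(sprintf("ring at radius %d px has no valid data; left invalid",
                        ring), call. = FALSE)
        next
      }
      intens[on_ring] <- interp_ring(coords$azimuth_deg[on_ring], v)
    }
  }
  out <- saxs_pattern(intens, source = p$source)
  out$annulus <- p$annulus
  out
}
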