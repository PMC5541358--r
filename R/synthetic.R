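# Synthetic fibre-diffraction patterns with known ground truth. The model
# composes the same terms the analysis assumes: a power-law diffuse
# background a*R^b, an equatorial term G(K) * F^2(K) with a liquid-like
# interference function G(K) = 1 + amp * Gaussian(K0, sigma) modulated by a
# 180-degree-symmetric azimuthal envelope, and meridional Bragg arcs of the
# axial D-period at K = 2*pi*n/D. Before gaps/noise the pattern has exact
# order-2 rotational symmetry about the centre (the centre defaults to a
# half-integer position so point reflection maps pixels onto pixels).

#' Specification for a synthetic collagen SAXS pattern
#'
#' Defaults describe a hydrated-tendon-like specimen on a 512 x 512
#' detector: axial D-period 67 nm with meridional orders 1 and 3, fibril
#' radius 19.1 nm (diameter 38.2 nm), equatorial interference peak at a
#' Bragg spacing of 55 nm, and a power-law background. The calibration
#' constant 0.0015 nm^-1/px places the relevant peaks between ~60 and
#' ~190 px, inside the detector edge.
#'
#' @param shape detector `(rows, cols)`.
#' @param centre beam centre `(row, col)`; half-integer coordinates keep
#'   the order-2 point reflection pixel-exact.
#' @param k_per_pixel calibration constant (nm^-1 per pixel).
#' @param d_period_nm axial D-period (nm).
#' @param meridional_orders integer orders of the meridional reflections.
#' @param meridional_amp peak amplitude (counts) per order.
#' @param meridional_width_px radial Gaussian sigma of the arcs (px).
#' @param meridional_az_sigma_deg azimuthal Gaussian sigma of the arcs.
#' @param meridional_az_deg azimuth of the meridian (fibre axis direction).
#' @param fibril_radius_nm cylinder radius r (nm); diameter = 2 r.
#' @param interference_d_nm Bragg spacing of the interference peak (nm).
#' @param interference_sigma_k Gaussian sigma of that peak (nm^-1).
#' @param interference_rel_amp peak amplitude of G relative to its
#'   liquid-like baseline of 1.
#' @param equatorial_amp overall equatorial scale (counts).
#' @param orientation_lobes `NULL` for an isotropic azimuthal envelope, or
#'   a list of lobes `list(mu_deg=, kappa=, weight=)`; each lobe is a von
#'   Mises pair at `mu` and `mu + 180` so the envelope is 180-degree
#'   symmetric.
#' @param powerlaw_a,powerlaw_b background constants of `a * R^b`.
#' @param poisson sample each pixel from a Poisson law with the model mean?
#' @param seed RNG seed used when `poisson = TRUE`.
#' @param gaps list of invalid rectangles `c(row1, row2, col1, col2)`
#'   emulating detector-module gaps.
#' @param beamstop_radius_px pixels closer to the centre than this are
#'   invalid (beamstop shadow); 0 disables.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(512L, 512L),
                           centre = c(256.5, 256.5),
                           k_per_pixel = 0.0015,
                           d_period_nm = 67,
                           meridional_orders = c(1L, 3L),
                           meridional_amp = c(4000, 2000),
                           meridional_width_px = 2,
                           meridional_az_sigma_deg = 5,
                           meridional_az_deg = 90,
                           fibril_radius_nm = 19.1,
                           interference_d_nm = 55,
                           interference_sigma_k = 0.005,
                           interference_rel_amp = 3,
                           equatorial_amp = 5000,
                           orientation_lobes = NULL,
                           powerlaw_a = 5e5, powerlaw_b = -1.8,
                           poisson = FALSE, seed = 1L,
                           gaps = NULL, beamstop_radius_px = 0) {
  spec <- as.list(environment())
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  edge <- min(spec$centre[1] - 0.5, spec$shape[1] + 0.5 - spec$centre[1],
              spec$centre[2] - 0.5, spec$shape[2] + 0.5 - spec$centre[2])
  need <- c(
    interference = (2 * pi / spec$interference_d_nm) / spec$k_per_pixel,
    subsidiary = cylinder_maxima(1) / (spec$k_per_pixel * spec$fibril_radius_nm),
    meridional = max(spec$meridional_orders) * (2 * pi / spec$d_period_nm) /
      spec$k_per_pixel)
  if (any(need > edge - 10))
    saxs_validation_error(sprintf(
      "peak at %.1f px lies outside the usable detector radius (%.1f px)",
      max(need), edge - 10))
  if (length(spec$meridional_amp) != length(spec$meridional_orders))
    saxs_validation_error("meridional_amp must match meridional_orders in length")
  invisible(spec)
}

angular_envelope <- function(az_deg, lobes) {
  if (is.null(lobes)) return(rep(1, length(az_deg)))
  phi <- az_deg * pi / 180
  out <- 0
  for (lb in lobes) {
    mu <- lb$mu_deg * pi / 180
    dvm <- function(m) exp(lb$kappa * cos(phi - m)) /
      (2 * pi * besselI(lb$kappa, 0))
    out <- out + lb$weight * pi * (dvm(mu) + dvm(mu + pi))  # mean weight over circle
  }
  out
}

wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Generate a synthetic pattern with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `pattern` (a [saxs_pattern()]) and `truth`
#'   (all planted values plus derived pixel positions of each feature).
#' @export
generate_pattern <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  coords <- radial_coordinate(spec$shape, spec$centre)
  R <- pmax(coords$radius, 0.5)   # guard R = 0 at an integer centre
  K <- spec$k_per_pixel * R

  bg <- spec$powerlaw_a * R^spec$powerlaw_b
  K0 <- 2 * pi / spec$interference_d_nm
  G <- 1 + spec$interference_rel_amp *
    exp(-(K - K0)^2 / (2 * spec$interference_sigma_k^2))
  F2 <- cylinder_shape(K * spec$fibril_radius_nm)
  env <- angular_envelope(coords$azimuth_deg, spec$orientation_lobes)
  intensity <- bg + spec$equatorial_amp * env * G * F2

  merid_px <- spec$meridional_orders * (2 * pi / spec$d_period_nm) /
    spec$k_per_pixel
  for (i in seq_along(spec$meridional_orders)) {
    radial <- exp(-(coords$radius - merid_px[i])^2 /
                  (2 * spec$meridional_width_px^2))
    d1 <- wrap_deg(coords$azimuth_deg - spec$meridional_az_deg)
    d2 <- wrap_deg(coords$azimuth_deg - spec$meridional_az_deg - 180)
    ang <- exp(-d1^2 / (2 * spec$meridional_az_sigma_deg^2)) +
           exp(-d2^2 / (2 * spec$meridional_az_sigma_deg^2))
    intensity <- intensity + spec$meridional_amp[i] * radial * ang
  }

  if (spec$poisson) {
    set.seed(spec$seed)
    intensity[] <- stats::rpois(length(intensity), intensity)
  }

  valid <- matrix(TRUE, spec$shape[1], spec$shape[2])
  if (!is.null(spec$gaps))
    for (g in spec$gaps)
      valid[g[1]:g[2], g[3]:g[4]] <- FALSE
  if (spec$beamstop_radius_px > 0)
    valid[coords$radius < spec$beamstop_radius_px] <- FALSE

  truth <- list(
    centre = spec$centre,
    k_per_pixel = spec$k_per_pixel,
    d_period_nm = spec$d_period_nm,
    fibril_radius_nm = spec$fibril_radius_nm,
    fibril_diameter_nm = 2 * spec$fibril_radius_nm,
    interference_d_nm = spec$interference_d_nm,
    powerlaw_a = spec$powerlaw_a, powerlaw_b = spec$powerlaw_b,
    calibrant_px = (2 * pi / spec$d_period_nm) / spec$k_per_pixel,
    interference_px = K0 / spec$k_per_pixel,
    subsidiary_px = cylinder_maxima(1) /
      (spec$k_per_pixel * spec$fibril_radius_nm),
    meridional_px = merid_px,
    meridional_orders = spec$meridional_orders,
    orientation_mu_deg = if (is.null(spec$orientation_lobes)) NULL
      else vapply(spec$orientation_lobes, `[[`, 0, "mu_deg"))

  list(pattern = saxs_pattern(ifelse(valid, intensity, NA_real_),
                              source = "synthetic"),
       truth = truth)
}

#' Generate a synthetic calibrant pattern
#'
#' A ring pattern mimicking an azimuthally complete calibrant exposure
#' (such as hydrated rat-tail tendon imaged through a full rotation): a
#' Gaussian ring of known radius on a flat background, suitable for
#' [fit_circle()] on sampled ring points and for [make_calibration()].
#'
#' @param shape detector `(rows, cols)`.
#' @param centre ring centre `(row, col)`.
#' @param ring_radius_px ring radius (pixels).
#' @param ring_sigma_px radial Gaussian sigma of the ring.
#' @param amp ring amplitude (counts).
#' @param background flat background level (counts).
#' @return list with `pattern` and `truth` (centre and ring radius).
#' @export
generate_calibrant <- function(shape = c(512L, 512L), centre = c(256.5, 256.5),
                               ring_radius_px = 100, ring_sigma_px = 2,
                               amp = 1000, background = 10) {
  coords <- radial_coordinate(shape, centre)
  intensity <- background +
    amp * exp(-(coords$radius - ring_radius_px)^2 / (2 * ring_sigma_px^2))
  list(pattern = saxs_pattern(intensity, source = "synthetic_calibrant"),
       truth = list(centre = centre, ring_radius_px = ring_radius_px))
}

#' Write a generated pattern and its ground-truth sidecar
#'
#' The image goes to `<name>.tif` (32-bit float TIFF) and the ground truth
#' to `<name>.json`.
#'
#' @param gen a [generate_pattern()] (or [generate_calibrant()]) result.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return the image path, invisibly.
#' @export
write_synthetic <- function(gen, dir, name = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- file.path(dir, paste0(name, ".tif"))
  write_pattern(gen$pattern, img)
  jsonlite::write_json(gen$truth, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(img)
}
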