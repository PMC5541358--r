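# Fixtures are built in code: patterns as analytic fields of (radius,
# azimuth), plus a config factory matched to a synthetic ground truth.

# pattern whose intensity is f(radius, azimuth_deg) about `centre`
field_pattern <- function(shape, centre, f, source = "field") {
  co <- radial_coordinate(shape, centre)
  m <- f(co$radius, co$azimuth_deg)
  saxs_pattern(matrix(m, shape[1], shape[2]), source = source)
}

# first two zeros of J1, used to anchor background fits where the
# equatorial term of the synthetic model vanishes
J1_ZERO_1 <- 3.8317059702
J1_ZERO_2 <- 7.0155866698

# pipeline config matched to a generate_pattern() ground-truth record
config_for_truth <- function(truth, init_r_nm = 18) {
  cfg <- default_config()
  cfg$centre$fixed <- truth$centre
  cfg$calibration$peak_pixel <- truth$calibrant_px
  cfg$calibration$d_nm <- truth$d_period_nm
  kr <- truth$k_per_pixel * truth$fibril_radius_nm
  cfg$background$fit_radii <- c(J1_ZERO_1, J1_ZERO_2) / kr
  n <- length(truth$meridional_px)
  cfg$peaks$meridional_guess_px <- truth$meridional_px[n]
  cfg$peaks$meridional_order <- truth$meridional_orders[n]
  cfg$peaks$interfib_guess_px <- truth$interference_px
  cfg$cylinder$r_nm <- init_r_nm
  cfg$orientation$r_inner <- truth$interference_px - 16
  cfg$orientation$r_outer <- truth$interference_px + 16
  cfg
}

# Gaussian-peak radial profile on an integer grid
gaussian_profile <- function(centre_px = 120, sigma = 5, height = 200,
                             baseline = 0, r = 1:300) {
  structure(data.frame(radius_px = r,
                       intensity = baseline +
                         height * exp(-(r - centre_px)^2 / (2 * sigma^2)),
                       n_valid = 1L),
            class = c("radial_profile", "data.frame"))
}

expect_saxs_error <- function(expr, class) expect_error(expr, class = class)
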