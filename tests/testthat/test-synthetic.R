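test_that("noiseless generation is deterministic; Poisson runs reproduce under a seed", {
  spec <- synthetic_spec(shape = c(128L, 128L), centre = c(64.5, 64.5),
                         k_per_pixel = 0.006)
  a <- generate_pattern(spec); b <- generate_pattern(spec)
  expect_identical(a$pattern$intensity, b$pattern$intensity)
  expect_identical(a$truth, b$truth)

  spec$poisson <- TRUE
  p1 <- generate_pattern(spec); p2 <- generate_pattern(spec)
  expect_identical(p1$pattern$intensity, p2$pattern$intensity)
  spec$seed <- 2L
  p3 <- generate_pattern(spec)
  expect_false(identical(p1$pattern$intensity, p3$pattern$intensity))
})

test_that("the equator of a generated pattern matches the closed form to 1e-9", {
  spec <- synthetic_spec()
  gen <- generate_pattern(spec)
  # pixels straight to the right of the centre: azimuth 0, radius = offset
  row0 <- 257  # centre row 256.5 -> rows 256/257 are half a pixel off-axis
  cols <- 300:450
  co <- radial_coordinate(spec$shape, spec$centre)
  R <- co$radius[row0, cols]
  K <- spec$k_per_pixel * R
  G <- 1 + spec$interference_rel_amp *
    exp(-(K - 2 * pi / spec$interference_d_nm)^2 /
        (2 * spec$interference_sigma_k^2))
  x <- K * spec$fibril_radius_nm
  F2 <- (2 * besselJ(x, 1) / x)^2
  closed <- spec$powerlaw_a * R^spec$powerlaw_b +
    spec$equatorial_amp * G * F2
  merid <- gen$truth$meridional_px
  az <- co$azimuth_deg[row0, cols]
  for (i in seq_along(merid)) {  # meridional arcs at 90/270 deg: tiny but finite here
    radial <- exp(-(R - merid[i])^2 / (2 * spec$meridional_width_px^2))
    d1 <- ((az - 90 + 180) %% 360) - 180
    d2 <- ((az - 270 + 180) %% 360) - 180
    closed <- closed + spec$meridional_amp[i] * radial *
      (exp(-d1^2 / (2 * spec$meridional_az_sigma_deg^2)) +
       exp(-d2^2 / (2 * spec$meridional_az_sigma_deg^2)))
  }
  expect_equal(gen$pattern$intensity[row0, cols], closed, tolerance = 1e-9)
})

test_that("generated patterns have exact order-2 symmetry before gaps/noise", {
  spec <- synthetic_spec(shape = c(256L, 256L), centre = c(128.5, 128.5),
                         k_per_pixel = 0.003,
                         orientation_lobes = list(
                           list(mu_deg = 20, kappa = 2, weight = 1)))
  m <- generate_pattern(spec)$pattern$intensity
  expect_equal(m, m[256:1, 256:1], tolerance = 1e-12)
})

test_that("inconsistent specs are rejected", {
  expect_saxs_error(synthetic_spec(k_per_pixel = 1e-4),  # peaks beyond edge
                    "saxs_validation_error")
  expect_saxs_error(synthetic_spec(meridional_amp = 1),
                    "saxs_validation_error")
})

test_that("a calibrant ring yields the centre and the calibration constant", {
  truth_centre <- c(251.25, 259.75)
  cal_gen <- generate_calibrant(shape = c(512L, 512L), centre = truth_centre,
                                ring_radius_px = 100)
  # seven points clicked around the ring: nearest bright pixel per azimuth
  az <- seq(0, 300, by = 50) * pi / 180
  pts <- cbind(truth_centre[1] - 100 * sin(az), truth_centre[2] + 100 * cos(az))
  fit <- fit_circle(pts)
  expect_equal(unname(fit$centre), truth_centre, tolerance = 1e-6)

  prof <- integrate_radial(cal_gen$pattern, fit$centre)
  guess <- prof$radius_px[which.max(prof$intensity)]
  peak <- find_nearest_peak(prof, guess)
  expect_equal(peak$position_px, 100, tolerance = 1e-3)
  cal <- make_calibration(peak$position_px, 67)
  expect_equal(cal$k_per_pixel, 2 * pi / 67 / 100, tolerance = 1e-4)
})

test_that("after gap filling, profiles differ from a gap-free run by < 0.5% RMS", {
  spec <- synthetic_spec()
  clean <- generate_pattern(spec)$pattern
  spec$gaps <- list(c(200L, 216L, 1L, 512L))
  spec$beamstop_radius_px <- 12
  gappy <- generate_pattern(spec)$pattern
  expect_false(all(gappy$valid))
  filled <- suppressWarnings(fill_gaps(gappy, spec$centre))
  a <- integrate_radial(clean, spec$centre, r_min = 14, r_max = 250)
  b <- integrate_radial(filled, spec$centre, r_min = 14, r_max = 250)
  rms <- sqrt(mean((b$intensity - a$intensity)^2, na.rm = TRUE)) /
    sqrt(mean(a$intensity^2))
  expect_lt(rms, 0.005)
})

test_that("synthetic images round-trip through the float-TIFF sidecar layout", {
  dir <- withr::local_tempdir()
  gen <- generate_pattern(synthetic_spec(shape = c(128L, 128L),
                                         centre = c(64.5, 64.5),
                                         k_per_pixel = 0.006,
                                         gaps = list(c(30L, 34L, 1L, 128L))))
  img <- write_synthetic(gen, dir, "demo")
  expect_true(file.exists(img))
  back <- load_pattern(img)
  expect_identical(back$valid, gen$pattern$valid)
  expect_equal(back$intensity[back$valid], gen$pattern$intensity[gen$pattern$valid],
               tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "demo.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$interference_d_nm, 55)
  expect_equal(truth$fibril_diameter_nm, 38.2)
})
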