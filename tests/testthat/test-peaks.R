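test_that("nearest-maximum search refines a Gaussian peak and its width", {
  prof <- gaussian_profile(centre_px = 120, sigma = 5, height = 200)
  peak <- find_nearest_peak(prof, guess_px = 112)
  expect_equal(peak$position_px, 120, tolerance = 0.1 / 120)
  expect_equal(peak$height, 200, tolerance = 0.01)
  # closed-form FWHM of a Gaussian
  expect_equal(peak$hhw_px, 2 * sqrt(2 * log(2)) * 5, tolerance = 0.01)
  expect_lt(peak$left_px, peak$position_px)
  expect_gt(peak$right_px, peak$position_px)

  # guess exactly at the maximum returns that maximum
  at_max <- find_nearest_peak(prof, guess_px = 120)
  expect_equal(at_max$position_px, peak$position_px)

  # nearest of two maxima wins
  two <- prof
  two$intensity <- two$intensity +
    150 * exp(-(two$radius_px - 140)^2 / (2 * 4^2))
  expect_equal(find_nearest_peak(two, 134, window_px = 25)$position_px, 140,
               tolerance = 1e-2)
})

test_that("peak search failure modes are classed", {
  flat <- gaussian_profile(height = 0, baseline = 10)
  expect_saxs_error(find_nearest_peak(flat, 100), "saxs_peak_error")
  prof <- gaussian_profile()
  expect_saxs_error(find_nearest_peak(prof, 1e5), "saxs_validation_error")
  # peak next to the profile edge: half-height crossing unreachable
  edge <- gaussian_profile(centre_px = 4, sigma = 5, r = 1:60)
  expect_warning(pk <- find_nearest_peak(edge, 5), "HHW undefined")
  expect_true(is.na(pk$hhw_px))
  expect_true(is.na(order_parameter(pk)))
})

test_that("order parameter is height over HHW with the expected scalings", {
  prof <- gaussian_profile(centre_px = 120, sigma = 5, height = 200)
  peak <- find_nearest_peak(prof, 120)
  op <- order_parameter(peak)
  expect_equal(op, peak$height / peak$hhw_px)
  expect_equal(op, 200 / 11.7741, tolerance = 1e-3)

  doubled <- prof; doubled$intensity <- 2 * doubled$intensity
  expect_equal(order_parameter(find_nearest_peak(doubled, 120)), 2 * op,
               tolerance = 1e-9)

  broader <- find_nearest_peak(gaussian_profile(sigma = 8), 120)
  expect_lt(order_parameter(broader), op)
})

test_that("cylinder transform matches its defining formula and limits", {
  model <- cylinder_transform(19.1, amplitude = 3)
  K <- seq(0, 0.6, by = 1e-4)
  # brute-force oracle straight from the definition
  x <- K * 19.1
  oracle <- ifelse(x == 0, 3, 3 * (2 * besselJ(x, 1) / x)^2)
  expect_equal(eval_cylinder_transform(model, K), oracle, tolerance = 1e-12)
  expect_equal(eval_cylinder_transform(model, 0), 3)
  expect_true(all(eval_cylinder_transform(model, K) >= 0))

  # first zero of F^2 at K*r = 3.8317 (first zero of J1)
  vals <- eval_cylinder_transform(model, K[-1])
  expect_equal(K[-1][which.min(vals[x[-1] < 5])] * 19.1, 3.8317,
               tolerance = 1e-3)
})

test_that("subsidiary maxima of the cylinder transform sit at 5.14 and 8.42", {
  mx <- cylinder_maxima(2)
  expect_equal(round(mx[1], 2), 5.14)
  expect_equal(round(mx[2], 2), 8.42)
  # positions are amplitude-invariant by construction of the model
  m1 <- cylinder_transform(10, 1); m2 <- cylinder_transform(10, 250)
  Kg <- seq(0.4, 0.65, by = 1e-5)
  expect_equal(Kg[which.max(eval_cylinder_transform(m1, Kg))],
               Kg[which.max(eval_cylinder_transform(m2, Kg))])
})

test_that("auto cylinder fit recovers radius and amplitude from its own curve", {
  cal <- make_calibration(62.51726, 67)   # 0.0015 nm^-1/px
  r_px <- 1:250
  truth <- cylinder_transform(19.1, amplitude = 40)
  prof <- structure(data.frame(radius_px = r_px,
                               intensity = eval_cylinder_transform(
                                 truth, k_from_pixel(cal, r_px)),
                               n_valid = 1L),
                    class = c("radial_profile", "data.frame"))
  fit <- fit_cylinder_transform(prof, cal, init_r_nm = 17)
  expect_true(fit$converged)
  expect_equal(fit$r_nm, 19.1, tolerance = 0.005)
  expect_equal(2 * fit$r_nm, 38.2, tolerance = 0.005 * 38.2)
  expect_equal(fit$amplitude, 40, tolerance = 0.02)

  # scaling the profile scales the amplitude, not the radius
  scaled <- prof; scaled$intensity <- 5 * scaled$intensity
  fs <- fit_cylinder_transform(scaled, cal, init_r_nm = 17)
  expect_equal(fs$r_nm, fit$r_nm, tolerance = 1e-3)
  expect_equal(fs$amplitude, 5 * fit$amplitude, tolerance = 0.05)

  # manual mode uses the supplied values verbatim
  man <- fit_cylinder_transform(prof, cal, 21.5, 7, mode = "manual")
  expect_equal(coef(man), c(r_nm = 21.5, amplitude = 7))
})

test_that("a subsidiary maximum at pixel R_b implies r = 5.14 / K(R_b)", {
  cal <- make_calibration(100, 67)
  r_nm <- 22.4
  x1 <- cylinder_maxima(1)
  R_b <- x1 / (cal$k_per_pixel * r_nm)
  expect_equal(x1 / k_from_pixel(cal, R_b), r_nm, tolerance = 1e-12)
})

test_that("Bessel compensation inverts a multiplicative construction", {
  cal <- make_calibration(62.51726, 67)
  r_px <- 1:250
  K <- k_from_pixel(cal, r_px)
  model <- cylinder_transform(19.1, amplitude = 12)
  F2 <- eval_cylinder_transform(model, K)
  G0 <- 1 + 4 * exp(-(K - 0.114)^2 / (2 * 0.01^2))
  prof <- structure(data.frame(radius_px = r_px, intensity = G0 * F2,
                               n_valid = 1L),
                    class = c("radial_profile", "data.frame"))
  G <- bessel_compensate(prof, model, cal)
  ok <- !is.na(G$intensity)
  expect_true(any(ok) && !all(ok))
  expect_equal(G$intensity[ok], G0[ok], tolerance = 1e-6)

  # bins at the first J1 zero are excluded
  zero_px <- 3.8317 / (cal$k_per_pixel * 19.1)
  expect_true(is.na(G$intensity[round(zero_px)]))

  # re-multiplication reproduces the input exactly on defined bins
  back <- G$intensity[ok] * F2[ok]
  expect_equal(back, prof$intensity[ok], tolerance = 1e-12)

  # F^2 over itself is one
  self <- prof; self$intensity <- F2
  Gs <- bessel_compensate(self, model, cal)
  expect_equal(Gs$intensity[!is.na(Gs$intensity)],
               rep(1, sum(!is.na(Gs$intensity))))

  expect_saxs_error(bessel_compensate(prof, model, cal, epsilon = 1e9),
                    "saxs_empty_data_error")
})

test_that("structure parameters calibrate peak positions and mark absences", {
  cal <- make_calibration(100, 67)
  mer <- structure(list(position_px = 300, height = 50, hhw_px = 10,
                        left_px = 295, right_px = 305),
                   class = "peak_measurement")
  inter <- structure(list(position_px = 150, height = 80, hhw_px = 8,
                          left_px = 146, right_px = 154),
                     class = "peak_measurement")
  cyl <- cylinder_transform(19.1, 5)
  sp <- compute_structure_params(cal, mer, 3L, inter, cylinder = cyl)
  expect_equal(sp$d_period_nm, 67)
  expect_equal(sp$bragg_spacing_nm, 67 * 100 / 150)  # 44.667 nm
  expect_equal(sp$fibril_diameter_nm, 38.2)
  expect_equal(sp$order_param, 10)
  expect_true(is.na(sp$bragg_spacing_comp_nm))
  expect_true(is.na(sp$order_param_comp))

  none <- compute_structure_params(cal)
  expect_true(all(is.na(unlist(none))))
})
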