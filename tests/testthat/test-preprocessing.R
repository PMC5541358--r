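test_that("negative correction shifts by the minimum and preserves differences", {
  p <- saxs_pattern(matrix(c(-1, 3, 0, 7), 2, 2))
  out <- correct_negative(p)
  expect_equal(out$intensity, matrix(c(0, 4, 1, 8), 2, 2))

  pos <- saxs_pattern(matrix(c(2, 3, 4, 5), 2, 2))
  expect_identical(correct_negative(pos), pos)

  const <- correct_negative(saxs_pattern(matrix(-5, 3, 3)))
  expect_true(all(const$intensity == 0))

  set.seed(3)
  m <- matrix(rnorm(100, sd = 10), 10, 10)
  out <- correct_negative(saxs_pattern(m))
  expect_equal(diff(as.vector(out$intensity)), diff(as.vector(m)))
})

test_that("background image subtraction is pixelwise with mask intersection", {
  p <- saxs_pattern(matrix(c(4, 5, 6, 7), 2, 2))
  expect_identical(subtract_background_image(p, NULL), p)

  zero <- saxs_pattern(matrix(0, 2, 2))
  expect_equal(subtract_background_image(p, zero)$intensity, p$intensity)

  expect_true(all(subtract_background_image(p, p)$intensity == 0))

  expect_equal(subtract_background_image(saxs_pattern(matrix(4, 1, 1)),
                                         saxs_pattern(matrix(2, 1, 1)),
                                         scale = 0.5)$intensity,
               matrix(3, 1, 1))

  bg <- saxs_pattern(matrix(c(1, NA, 1, 1), 2, 2))
  expect_identical(subtract_background_image(p, bg)$valid,
                   matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))

  expect_saxs_error(subtract_background_image(p, saxs_pattern(matrix(0, 3, 3))),
                    "saxs_validation_error")
})

test_that("threshold masking invalidates outliers and never alters survivors", {
  m <- matrix(c(1, 5, 6.05, 6.2, 8, 100), 2, 3)
  p <- saxs_pattern(m)
  out <- apply_mask(p, mask_spec(ll = 6.1, ul = 50))
  expect_identical(out$valid, m >= 6.1 & m <= 50)
  expect_identical(out$intensity[out$valid], m[m >= 6.1 & m <= 50])

  expect_identical(apply_mask(p, mask_spec())$valid, p$valid)

  all_low <- apply_mask(p, mask_spec(ll = 1000))
  expect_false(any(all_low$valid))
  expect_saxs_error(integrate_radial(all_low, c(1.5, 2)),
                    "saxs_empty_data_error")

  expect_saxs_error(mask_spec(ll = 5, ul = 5), "saxs_validation_error")
  expect_saxs_error(mask_spec(ri = 10, rio = 5), "saxs_validation_error")
  expect_equal(apply_mask(p, mask_spec(ri = 10, rio = 40))$annulus, c(10, 40))
})

test_that("order-2 symmetry pass restores masked blocks exactly", {
  centre <- c(32.5, 32.5)
  f <- function(r, az) 5 + r^1.3 + 40 * cos(2 * az * pi / 180) * exp(-r / 30)
  p <- field_pattern(c(64, 64), centre, f)
  masked <- p$intensity
  masked[10:20, 5:25] <- NA       # partner block (45:55, 40:60) stays valid
  pm <- saxs_pattern(masked)
  filled <- fill_gaps(pm, centre)
  expect_true(all(filled$valid))
  expect_equal(filled$intensity, p$intensity, tolerance = 1e-9)
})

test_that("circumferential interpolation is linear in azimuth on a ring", {
  centre <- c(41.5, 41.5)
  co <- radial_coordinate(c(82, 82), centre)
  p <- saxs_pattern(co$azimuth_deg)  # intensity equals azimuth in degrees
  ring <- round(co$radius) == 25
  # mask a gap AND its symmetric partner so pass 1 cannot help
  gap <- ring & ((co$azimuth_deg > 10 & co$azimuth_deg < 20) |
                 (co$azimuth_deg > 190 & co$azimuth_deg < 200))
  m <- p$intensity; m[gap] <- NA
  filled <- fill_gaps(saxs_pattern(m), centre)
  expect_true(all(filled$valid))
  # linear interpolation of azimuth-valued data reproduces the azimuth
  expect_equal(filled$intensity[gap], p$intensity[gap], tolerance = 1e-9)
  expect_identical(filled$intensity[!gap], p$intensity[!gap])
})

test_that("gap filling is idempotent and identity on complete patterns", {
  centre <- c(24.5, 24.5)
  p <- field_pattern(c(48, 48), centre, function(r, az) r + sin(2 * az * pi / 180))
  expect_identical(fill_gaps(p, centre), p)

  m <- p$intensity
  set.seed(9)
  m[sample(which(col(m) <= 20), 150)] <- NA
  once <- fill_gaps(saxs_pattern(m), centre)
  twice <- fill_gaps(once, centre)
  expect_identical(twice$intensity, once$intensity)
})

test_that("a fully invalid ring is left invalid with a warning", {
  centre <- c(21.5, 21.5)
  co <- radial_coordinate(c(42, 42), centre)
  m <- co$radius + 7
  m[round(co$radius) == 12] <- NA
  expect_warning(filled <- fill_gaps(saxs_pattern(m), centre), "no valid data")
  expect_false(any(filled$valid[round(co$radius) == 12]))
  expect_true(all(filled$valid[round(co$radius) != 12]))
})
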