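#' Fit a power-law background to a radial profile
#'
#' Diffuse background scatter in fibrous-collagen SAXS follows
#' `I(R) = a * R^b` to good approximation over the peak region. The fit is
#' a least-squares straight line through `(ln R, ln I)` at user-chosen
#' anchor radii (three points is the customary choice; any >= 2 distinct
#' radii are accepted): `a = exp(intercept)`, `b = slope`. With two
#' distinct points the line is exact.
#'
#' @param profile a `radial_profile` from [integrate_radial()].
#' @param radii numeric vector (length >= 2) of anchor radii in pixels;
#'   each is matched to the nearest profile bin.
#' @return Object of class `powerlaw_fit`: list with `a`, `b`,
#'   `fit_points` (the bin radii actually used).
#' @export
fit_power_law <- function(profile, radii) {
  stopifnot(inherits(profile, "radial_profile"))
  if (length(radii) < 2L)
    saxs_validation_error("power-law fit needs at least 2 anchor radii")
  idx <- vapply(radii, function(r) which.min(abs(profile$radius_px - r)), 0L)
  R <- profile$radius_px[idx]
  I <- profile$intensity[idx]
  if (anyNA(I))
    saxs_validation_error("anchor point falls in a bin with no data")
  if (any(I <= 0) || any(R <= 0))
    saxs_abort("anchor intensities must be strictly positive for the log-log fit",
               "saxs_log_domain_error")
  if (length(unique(R)) < 2L)
    saxs_validation_error("anchor radii must include at least 2 distinct bins")
  co <- stats::lm.fit(cbind(1, log(R)), log(I))$coefficients
  structure(list(a = unname(exp(co[1])), b = unname(co[2]), fit_points = R),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law background: I(R) = %.6g * R^%.6g  (anchors at %s px)\n",
              x$a, x$b, paste(signif(x$fit_points, 6), collapse = ", ")))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) c(a = object$a, b = object$b)

#' Evaluate a fitted power-law background
#'
#' @param object a `powerlaw_fit`.
#' @param radius radii (pixels) at which to evaluate.
#' @param ... unused.
#' @return `a * radius^b`.
#' @export
predict.powerlaw_fit <- function(object, radius, ...) {
  object$a * radius^object$b
}

#' Subtract a fitted power-law background from a radial profile
#'
#' Per-bin subtraction of `a * R^b`. Bins without data stay absent;
#' negative residuals are retained (clipping at zero would bias half-height
#' width measurement of weak peaks). Subtraction is not idempotent:
#' subtracting twice removes the background twice.
#'
#' @param profile a `radial_profile`.
#' @param bg a `powerlaw_fit`.
#' @return background-subtracted `radial_profile`.
#' @export
subtract_power_law <- function(profile, bg) {
  stopifnot(inherits(profile, "radial_profile"), inherits(bg, "powerlaw_fit"))
  profile$intensity <- profile$intensity - predict(bg, profile$radius_px)
  profile
}
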