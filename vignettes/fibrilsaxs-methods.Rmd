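---
title: "Reducing collagen SAXS patterns with fibrilsaxs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing collagen SAXS patterns with fibrilsaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilsaxs)
```

## The measurement and its model

Small-angle X-ray scattering (SAXS) from fibrous collagen tissue — cornea,
sclera, tendon, skin — encodes the nanometre-scale architecture of the
collagen fibrils in a 2D detector image. Two families of reflections carry
the structure:

* **Meridional** reflections, along the fibre axis, are Bragg orders of the
  axial D-period (about 67 nm in hydrated tendon); a reflection of order
  $n$ at radial pixel position $R$ corresponds to a spacing $n\,d(R)$.
* **Equatorial** scatter, perpendicular to the fibril axes, is modelled as
  the product
  $$ I(K) \;=\; G(K)\, F^2(K), $$
  where $K = 2\pi/d$ is the scattering-vector magnitude, $G(K)$ is the
  *interference function* of the fibril lattice (its peak gives the Bragg
  interfibrillar separation, to a first approximation), and $F^2$ is the
  *cylinder (fibril) transform* — the scattering of one long uniform
  cylinder of radius $r$:
  $$ F^2(K) \;=\; A \left[ \frac{2 J_1(K r)}{K r} \right]^2, $$
  normalized so $F(0) = 1$ (Oster–Riley convention; the choice of constant
  does not move any extremum, and only extrema positions enter the derived
  spacings). $F^2$ vanishes at the zeros of $J_1$ ($Kr = 3.8317, 7.0156,
  \dots$) and has subsidiary maxima at $Kr = 5.14, 8.42, \dots$ — the first
  subsidiary maximum is what ties an observed pixel position to the mean
  fibril radius.

Everything sits on a diffuse power-law background $I(R) = a R^{b}$, fitted
as a straight line in $(\ln R, \ln I)$ through user-chosen anchor radii.

The whole analysis works in pixel positions plus one calibration ratio, so
sample-to-detector distance and wavelength never appear: one calibrant
reflection of known spacing ($d_{cal}$, e.g. the 67 nm tendon first order)
at measured radius $r_{cal}$ fixes the small-angle linear mapping
$K(R) = (2\pi/d_{cal})\,R/r_{cal}$, i.e. $d(R) = d_{cal}\, r_{cal}/R$.

## Pipeline order and the preprocessing model

Stages run in a fixed order: load → negative-offset correction →
background-image subtraction → threshold (LL/UL) masking → symmetry gap
filling → integration. The threshold order relative to background-image
subtraction is a genuine free choice; we fix masking *after* subtraction
(thresholds then apply to the signal actually analysed) and treat it as a
config-visible convention.

Missing data (module gaps of tiled detectors, beamstop shadow, thresholded
outliers) are handled by the physics of the specimen: a fibre pattern with
negligible out-of-plane effects has order-2 rotational symmetry about the
beam centre, so pass 1 copies each invalid pixel from its point reflection
through the centre. The partner coordinate is rounded to the nearest pixel
— bilinear interpolation was rejected deliberately, because nearest-pixel
lookup is exactly value-preserving on symmetric input, which makes the
symmetry property testable as an identity. Pass 2 fills what remains by
linear interpolation in azimuth along each integer-radius ring, wrapping at
360°; a ring with no valid pixel at all cannot be interpolated and is left
invalid with a warning.

Profiles are **means** per bin, not sums. With gaps and masks, a sum
depends on how many pixels happened to survive in each bin; a mean does
not. The per-bin count `n_valid` is kept alongside, so sums are
recoverable as `intensity * n_valid` (a conservation identity the tests
assert). Bins are 1 px radially and 1° azimuthally by default, with
nearest-bin assignment of whole pixels (no area splitting). A side effect
of nearest-bin assignment worth knowing: with a half-integer beam centre,
1° azimuthal bins centred exactly on the axes can be empty near the
annulus radii where no pixel azimuth falls within ±0.5° of the axis; all
azimuthal consumers treat empty bins as absent and interpolate across them
circularly.

## Peak measurement

Peak detection is semi-automated in the same sense as an interactive tool:
the config supplies a guess, the software takes the nearest strict local
maximum within ±`window_px` (default 15 px; ties resolve toward smaller
radius), then refines the position and height by a 3-point parabola. The
half-height width (HHW) is measured by walking outward from the peak to
the two half-height crossings, each located by linear interpolation. We
read "half height width" as the **full** width at half height — both
crossings — because the original workflow marks detection limits on both
sides of the peak; a half-width reading would halve the denominator and
double every order parameter, so absolute order-parameter comparisons
across implementations should be made with that convention in mind. The
spatial-order parameter is `height / HHW` (arbitrary units), and is
reported as absent, never zero, when a crossing is not reached before the
profile edge or a data gap.

Bessel compensation divides the fitted $F^2$ out of the
background-subtracted equatorial profile to isolate $G(K)$. Near the zeros
of $J_1$ the division explodes, so bins with
$F^2 < \varepsilon \max F^2$ (default $\varepsilon = 10^{-3}$,
configurable) are marked undefined rather than clipped; the compensated
interfibrillar peak and order parameter are then re-measured on $G$ over
the defined bins.

The cylinder-transform fit has two modes. `manual` reproduces
slider-style adjustment: the configured $(r, A)$ are used verbatim.
`auto` refines both by least squares over a window around the expected
first subsidiary maximum (±15 px default), in log-parameters to keep both
positive; bins within ±6 px of a detected meridional peak are excluded
from that window, since a meridional arc radially close to the subsidiary
maximum would otherwise bias $r$. If the optimizer fails, the initial
values are kept with a warning — the batch keeps moving, as a retained
manual fit would.

## Orientation profiles

The preferentially aligned collagen at azimuth $\varphi$ is the radially
integrated, background-subtracted azimuthal profile minus its minimum (the
isotropic level). The power-law background is evaluated per pixel at that
pixel's radius before integration. The profile is smoothed by an exactly
zero-phase low-pass filter realized as Fourier truncation of the circular
signal (harmonics above `keep_harmonics`, default 12, are zeroed): among
"zero-phase low-pass" designs this is the only one that is simultaneously
exactly periodic, exactly zero-phase, idempotent and mean-preserving,
which turns the filter's contract into testable identities. Note the
azimuth plotted is the *scatter* azimuth; equatorial scatter is
perpendicular to the fibril axis, so fibril orientation is the same curve
rotated 90° (`rotate90` option, off by default).

Azimuth convention throughout: 0° along +columns, increasing
counter-clockwise in standard image display, pixel coordinates 1-based
(row, col) with row increasing downward. Plots from other tools may differ
by a rotation or reflection if they fixed a different origin.

## The synthetic generator: what it emulates, and what it does not

`generate_pattern()` composes exactly the terms the analysis assumes:
power-law background, an equatorial term
$A_{eq}\,E(\varphi)\,G(K)\,F^2(K)$, and meridional arcs (Gaussian in
radius, Gaussian in azimuth about the meridian, in symmetric pairs). The
defaults are a hydrated-tendon-like specimen on a 512×512 detector:
D-period 67 nm with orders 1 and 3, fibril radius 19.1 nm (diameter
38.2 nm), interference peak at 55 nm, calibration constant
0.0015 nm⁻¹/px (placing those features between ~60 and ~190 px), and
background $a = 5\times10^5$, $b = -1.8$, giving tens to hundreds of
counts per background pixel and a few thousand at the peaks — ordinary
synchrotron count levels where Poisson noise is visible but not dominant.

The interference function is modelled as
$G(K) = 1 + A_G \exp[-(K-K_0)^2/2\sigma_K^2]$ with $A_G = 3$ and
$\sigma_K = 0.005$ nm⁻¹. The liquid-like baseline of 1 matters twice:
it keeps the first subsidiary maximum of $F^2$ visible on the equatorial
profile (without it the auto cylinder fit would have no signal to fit),
and $A_G$ must exceed 1 for the peak of $G$ to rise above twice its
baseline so that half-height crossings exist on the compensated profile —
the regime in which the interfibrillar peak of real tissue is measurable
at all. The azimuthal envelope $E$ is a 180°-symmetric von Mises mixture,
the minimal model that produces the orthogonal-bimodal polar plots typical
of corneal collagen; `NULL` gives an isotropic specimen.

Before gaps and noise the generated pattern has *exact* order-2 symmetry
(the default centre is half-integer so point reflection maps pixels onto
pixels), which is what lets the gap-filling identity be asserted exactly.
Ground truth — every planted value plus the derived pixel positions — is
returned with the pattern and written as a JSON sidecar next to the float
TIFF.

What the generator does **not** emulate: fibril-diameter polydispersity,
instrument smearing / detector point-spread, solid-angle and polarization
corrections, and structured (non-power-law) cell backgrounds. Passing the
recovery tests therefore demonstrates the correctness of the reduction
chain under its own model assumptions, not robustness to every artefact of
beamline data.

## Numerical choices and degenerate inputs

* Raw peak position versus compensated: on $I = G\,F^2$ the raw
  interfibrillar maximum is shifted off the maximum of $G$ by the local
  slope of $F^2$ (upward in spacing, for a peak on the falling central
  lobe). That shift is physics, not error — removing it is what
  compensation is for — so recovery of the planted 55 nm is asserted on
  the compensated spacing, and the raw value is reported alongside.
* Circle fit: algebraic least squares (Kåsa). Exact on concyclic points,
  linear, deterministic, order-invariant; collinear input is a rank
  deficiency and raises a geometry error. No iterative refinement by
  default.
* Power-law fit: natural logs, ≥ 2 distinct anchors accepted (the
  customary three remain the default workflow); non-positive intensity at
  an anchor is a log-domain error. Residuals are not clipped at zero —
  clipping would bias HHW of weak peaks.
* Sub-pixel refinement by parabolic interpolation reduces the ~0.5 px
  quantization of whole-pixel maxima; at a 3rd-order meridional near
  190 px, 0.5 px is already 0.3% of the D-period, so refinement is what
  brings recovery comfortably within 1%.
* Degenerate inputs raise classed conditions (`saxs_empty_data_error`,
  `saxs_peak_error`, `saxs_geometry_error`, ...) so batch callers can
  distinguish "nothing to integrate" from "no peak here" without parsing
  messages; in the pipeline, analysis-stage failures degrade to absent
  fields while reduction-stage failures propagate with the stage name.
* Image I/O: integer TIFF/PNG pixels are promoted to real counts without
  rescaling; float TIFFs are read as stored. Written patterns go out as
  uncompressed 32-bit float TIFF with invalid pixels as NaN, so a write →
  load round trip preserves both values (at float32 precision) and the
  validity mask. RGB input is collapsed by unweighted channel mean with a
  warning — detector data should be single-channel, and no physically
  better weighting exists for false-colour exports.

## Problem sizes used in validation

The test-suite and the acceptance script validate on 512×512 synthetic
patterns (one noiseless, one Poisson-sampled run for recovery; 5-image
batches for batch/single equivalence), 250–400-bin profiles for the 1D
operations, and dense-grid scans of $[2J_1(x)/x]^2$ at $10^{-3}$ spacing
refined by golden-section search for the transform's extrema. These sizes
were chosen as the smallest at which every quantization effect the
defaults exhibit (1 px bins, 1° bins, half-integer centres) is present at
realistic scale.

## Known limitations

* The Bragg interfibrillar spacing is the first-approximation reading of
  the interference peak; the liquid-packing correction factor (~1.12) used
  in some of the literature is intentionally not applied.
* Absolute order parameters depend on the full-width HHW convention (see
  above) and on the $\varepsilon$-masking near $J_1$ zeros for the
  compensated variant; they are comparable within a processing
  configuration, not across tools.
* Calibration assumes the linear small-angle limit; at wide angles the
  $\tan 2\theta$ geometry would be needed.
* One pattern is analysed at a time; scanned-specimen orientation maps are
  out of scope.

## A worked miniature

```{r example}
gen <- generate_pattern(synthetic_spec())
cfg <- default_config()
cfg$centre$fixed <- gen$truth$centre
cfg$calibration$peak_pixel <- gen$truth$calibrant_px
cfg$calibration$d_nm <- 67
kr <- gen$truth$k_per_pixel * gen$truth$fibril_radius_nm
cfg$background$fit_radii <- c(3.8317, 7.0156) / kr
cfg$peaks$meridional_guess_px <- gen$truth$meridional_px[2]
cfg$peaks$meridional_order <- 3
cfg$peaks$interfib_guess_px <- gen$truth$interference_px
cfg$cylinder$r_nm <- 18
run <- run_single(cfg, gen$pattern)
run$params
```
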