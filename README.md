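# fibrilsaxs

Reduction and analysis of 2D small-angle X-ray scattering (SAXS) patterns
from fibrous collagen tissues — cornea, sclera, tendon, skin — from raw
detector image to calibrated structure parameters and collagen-orientation
polar profiles, scriptable and batch-capable.

## What it computes

SAXS from collagenous tissue shows meridional Bragg orders of the axial
D-period (≈67 nm in hydrated tendon) and equatorial scatter from lateral
fibril packing. The equatorial profile is modelled as

    I(K) = G(K) · F²(K),        K = 2π/d

where `G(K)` is the interference function of the fibril lattice (its peak
gives the Bragg interfibrillar spacing) and `F²` is the cylinder (fibril)
transform of one long uniform cylinder of radius `r`:

    F²(K) = A · [ 2 J₁(K r) / (K r) ]²

with subsidiary maxima at `K·r = 5.14, 8.42, …` — the first of which fixes
the mean fibril diameter `2r`. Diffuse background follows a power law
`I(R) = a·R^b`, fitted as a line through chosen anchors in ln–ln space.
Dividing the fitted `F²` out of the background-subtracted data ("Bessel
compensation") isolates `G(K)` for a cleaner spacing and order-parameter
reading. The relative spatial-order parameter is peak height divided by
the half-height width (HHW). Preferential collagen orientation is the
azimuthal profile of background-subtracted scatter minus its isotropic
(minimum) level, smoothed by an exactly zero-phase Fourier low-pass.

The pipeline covers: beam-centre determination by circle fit to ring
points; calibration from one calibrant reflection of known d-spacing;
negative-offset and background-image correction; outlier masking by
intensity thresholds; recovery of detector-gap data via the pattern's
order-2 rotational symmetry plus circumferential interpolation; NaN-aware
radial/azimuthal integration; and semi-automated peak detection (nearest
local maximum to a configured guess, sub-pixel refined). A synthetic
pattern generator with full ground truth makes every stage testable
without beamline data.

## Worked example

Generate the default synthetic specimen (512×512; D-period 67 nm via
orders 1 and 3; fibril diameter 38.2 nm; interference spacing 55 nm) and
run the full pipeline against it:

```r
library(fibrilsaxs)

gen <- generate_pattern(synthetic_spec())
cfg <- default_config()
cfg$centre$fixed              <- gen$truth$centre
cfg$calibration$peak_pixel    <- gen$truth$calibrant_px   # 67 nm first order
cfg$calibration$d_nm          <- 67
kr <- gen$truth$k_per_pixel * gen$truth$fibril_radius_nm
cfg$background$fit_radii      <- c(3.8317, 7.0156) / kr   # anchors at the J1 zeros
cfg$peaks$meridional_guess_px <- gen$truth$meridional_px[2]
cfg$peaks$meridional_order    <- 3
cfg$peaks$interfib_guess_px   <- gen$truth$interference_px
cfg$cylinder$r_nm             <- 18                       # deliberately off-truth start
run <- run_single(cfg, gen$pattern)
print(run)
```

```
SAXS run: synthetic  (stages: load > centre > negative_correction > mask >
  radial_profile > background_fit > cylinder_fit > bessel_compensation > structure_params)
Collagen structure parameters:
  D-period                   66.9235 nm
  fibril diameter            38.1925 nm
  Bragg spacing (raw)        55.3902 nm
  order parameter (raw)      522.5705 a.u.
  Bragg spacing (compensated) 54.9461 nm
  order parameter (compensated) 0.4003 a.u.
```

The D-period and (compensated) Bragg spacing land within 0.1% of the
planted 67 and 55 nm; the auto-fitted cylinder transform recovers the
fibril diameter within 0.02% from an initial guess 6% off. The raw Bragg
spacing (55.39 nm) is shifted off the planted value by the slope of `F²`
under the peak — exactly the bias that Bessel compensation removes. The
raw order parameter is in profile-intensity units (here thousands of
counts), the compensated one in units of the dimensionless `G`, so the
two are not directly comparable.

Batch mode applies one config across a directory
(`run_batch(cfg, "images/", "out/")`), writes a common `results.csv`, an
orientation CSV + polar-plot PNG per image, and a JSON run-log from which
any run can be replayed exactly (`run_from_log()`). A thin shell
front-end lives at `inst/cli/fibrilsaxs.R`:

```sh
Rscript inst/cli/fibrilsaxs.R synth --out demo/
Rscript inst/cli/fibrilsaxs.R run --config cfg.yaml --image demo/synthetic.tif --out demo_out/
Rscript inst/cli/fibrilsaxs.R batch --config cfg.yaml --dir images/ --out out/
```

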