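Package: fibrilsaxs
Title: Reduction and Analysis of Small-Angle X-Ray Scattering Patterns from
    Fibrous Collagen Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Batch-capable reduction of 2D small-angle X-ray scattering
    (SAXS) detector images from fibrous collagen specimens to calibrated
    structure parameters. Covers pattern centring by circle fitting,
    calibration from a calibrant reflection of known d-spacing, negative
    offset and background-image correction, outlier masking, recovery of
    detector-gap data by order-2 rotational symmetry and circumferential
    interpolation, azimuthal and radial integration, power-law background
    fitting in log-log space, semi-automated detection of meridional and
    equatorial peaks, cylinder-transform (Bessel J1) modelling and
    compensation of the equatorial interference function, and polar
    profiles of preferential collagen orientation. Includes a synthetic
    pattern generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
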