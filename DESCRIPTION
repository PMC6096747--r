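Package: tubecoord
Title: Lagrangian Cylindrical Coordinates for Tubular Anatomic Surfaces
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a Lagrangian cylindrical coordinate system (sigma, theta)
    on tubular anatomic surfaces defined by stacked cross-sectional lumen
    contours. A bifurcation-derived fiducial anchors a Greenwich curve that
    fixes the angular origin on every cross section, yielding a material
    (Lagrangian) surface parameterization r(sigma, theta). The package
    quantifies pointwise longitudinal and circumferential surface curvature
    by windowed three-point circle fitting, generalized cross-sectional
    eccentricity and its orientation, spirality, and pointwise differences
    between physiological states. Idealized software phantoms with known
    analytic geometry are included for validation, together with file I/O
    (structured JSON and CSV contour sets, CSV result tables, legacy-ASCII
    VTK surface export) and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
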