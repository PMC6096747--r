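# tubecoord

Lagrangian cylindrical coordinates for tubular anatomic surfaces.

Vascular morphology — surface curvature, cross-sectional eccentricity, and
how both change between physiological states — matters for diagnosis, for
device design, and for predicting device fatigue, which depends on
alternating strain at *material* points. `tubecoord` builds a material
(Lagrangian) cylindrical coordinate system on a tubular surface defined by
stacked cross-sectional lumen contours, the standard output of
centerline-plus-orthogonal-segmentation vessel modeling, and quantifies
its surface geometry pointwise. It is aimed at researchers analyzing
segmented CT/MR lumen geometry of vessels, stent grafts, or veins.

## The coordinate system

Given contours $S_i = \{b_{ij}\}$ with centroids $C_i$:

* $\sigma$ — signed arc length along the piecewise-linear centerline
  through the $C_i$ (mm), zero at the Greenwich contour;
* $\theta$ — in-plane polar angle about $C_i$ measured from the Greenwich
  direction, where the Greenwich point $\gamma$ is the boundary point
  closest to the fiducial $\delta$ (the most distal mother/daughter
  boundary intersection at a bifurcation) and is propagated along the
  vessel to form the Greenwich curve ($\theta = 0$ meridian);
* $r(\sigma, \theta)$ — the radial surface function, linearly interpolated
  in both coordinates; with a time tag, $r(\sigma, \theta, t)$.

On this grid the package computes:

* **directional curvature** $\kappa = 1/R$ of the circle through a surface
  point and its two symmetric window neighbors along $\sigma$ or $\theta$
  (windows: 30 mm and $\pi/4$ rad by default; cm$^{-1}$);
* **eccentricity** $e = \sqrt{1 - d^2/D^2}$ from the orthogonal centroid
  diameters minimizing $d/D$, with orientation $\theta_e$ of the major
  diameter relative to the Greenwich direction, and its spirality
  $d\theta_e/d\sigma$;
* **between-state difference maps** $|\kappa_a - \kappa_b|$ on the common
  material grid.

Two software phantoms with closed-form geometry (a simple 90° bend with
circular sections; a complex two-bend tube with elliptical sections and an
orientation transition) are included for validation.

## Worked example

```r
library(tubecoord)

ph <- generate_complex()                       # phantom + branch + analytic refs
an <- analyze_stack(ph$mother, branch = ph$branch, tolerance = 1)
an
#> greenwich frame: method 1, gamma on contour 5, curve length 224.90 mm
#> cylindrical surface: 42 contours, sigma in [-20.0, 184.8] mm
#> longitudinal curvature field: 42 contours, window 30 mm, range [0, 1.88] cm^-1 (576 masked)
#> circumferential curvature field: 42 contours, window 0.785 rad, range [0.255, 1.49] cm^-1 (0 masked)
```

The circumferential range shows the windowed ellipse readings: 0.255
cm⁻¹ on the flats (analytic 0.25) and 1.49 cm⁻¹ at the vertices — about
25% below the analytic 2.0, the known bias of a π/4 window on a tight
vertex. The eccentricity profile around the transition (centered at
σ = 96 mm):

```r
subset(an$profile, sigma > 85 & sigma < 111)
#>   sigma   D_mm   d_mm     e theta_e
#>  89.844 40.000 20.000 0.866   1.571
#>  94.844 29.993 29.993 0.000      NA
#>  99.844 37.939 22.061 0.814   0.038
#> 104.844 40.000 20.000 0.866   0.033
#> 109.844 40.000 20.000 0.866   0.033
```

`e` holds at √3/2 ≈ 0.866 on the elliptical sections, dips to 0 at the
circular throat (orientation undefined there), and the orientation flips
from π/2 (major axis perpendicular to the Greenwich direction) to ≈0.
The window study on the second bend's inner track (analytic peak
1.0 cm⁻¹):

```r
window_sweep(an$surface, ph$reference, "longitudinal", c(20, 30, 40),
             track_value = 1.0)[, c("window", "peak_computed", "peak_rel_error")]
#>   window peak_computed peak_rel_error
#> 1     20        1.0013         0.0013
#> 2     30        1.0004         0.0004
#> 3     40        0.8622         0.1378
```

The 30 mm window recovers the peak to 0.04%; a 40 mm window (wider than
the bend) underestimates it.

## Command line

```sh
Rscript -e 'tubecoord::tubecoord_cli()' phantom complex --out ph/
Rscript -e 'tubecoord::tubecoord_cli()' analyze --contours ph/mother.json \
    --fiducial-branch ph/branch.json --tolerance 1 --out results/
Rscript -e 'tubecoord::tubecoord_cli()' compare --a results_sys --b results_dia --out diff/
```

`analyze` writes per-node and per-contour CSV tables (units in headers),
the Greenwich curve, and a legacy-ASCII VTK surface with curvature
scalars.

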