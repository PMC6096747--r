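---
title: "Lagrangian cylindrical coordinates for tubular anatomic surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagrangian cylindrical coordinates for tubular anatomic surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A tubular anatomic surface (an aorta, an iliofemoral vein, a stent graft)
is represented by an ordered stack of closed cross-sectional lumen
contours $S_i = \{b_{ij}\}$, each a loop of 3D boundary points in a plane
approximately orthogonal to the vessel course. From this stack the package
builds a *material* (Lagrangian) cylindrical coordinate system:

* **Longitudinal coordinate $\sigma$.** The centroid $C_i$ of each contour
  is the arithmetic mean of its boundary points; the piecewise-linear
  polyline through the $C_i$ is the centerline, and $\sigma$ is signed
  cumulative arc length along it, zero at the Greenwich contour, negative
  proximally. Note this is the mean of the *sampled* points, not the area
  centroid: for strongly nonuniform boundary sampling the two differ, and
  the mean is what the coordinate system is defined on.
* **Angular coordinate $\theta$.** An angular origin must be fixed on
  every contour in a non-arbitrary way. A bifurcation provides the
  anchor: the most distal near-intersection of the mother and daughter
  lumen boundaries is the fiducial $\delta$; the boundary point closest to
  $\delta$ is the Greenwich point $\gamma$ on contour $k$; and $\gamma$ is
  propagated to every other contour, forming the Greenwich curve — the
  surface's prime meridian. $\theta$ is then the in-plane polar angle of a
  boundary point about $C_i$, measured from the direction
  $\gamma_i - C_i$, right-handed about the distal centerline tangent.
* **Radial surface function $r(\sigma, \theta)$.** Radial distance from
  the centroid to the surface, interpolated linearly in both coordinates
  (circularly across the $\theta$ seam). With a time tag this extends to
  $r(\sigma, \theta, t)$, and because the coordinates are material, maps
  computed at two physiological states can be differenced pointwise.

### Greenwich propagation

Three propagation rules are implemented (`propagate_greenwich`): (1)
translate $\gamma_i$ along the centerline chord $C_{i+1}-C_i$ to the next
contour plane and snap to the closest boundary point; (2) the same but
translating along the current contour's plane normal; (3) snap directly to
the closest boundary point. Method 1 is the default, as it tracks the
centerline most robustly; on a straight tube all three agree exactly (a
tested invariant). Proximal propagation mirrors the construction with
$C_{i-1}-C_i$. If a translation direction is parallel to the target plane
the step falls back to method 3 and logs a message. All tie-breaks
(closest point, fiducial candidates) resolve to the lowest contour index,
then the lowest point index, so results are deterministic.

### Curvature

Pointwise surface curvature is the reciprocal of the radius of the circle
through a surface point and its two symmetric window neighbors along
$\sigma$ (longitudinal) or $\theta$ (circumferential), computed via the
circumradius $R = abc/(4A)$. The *window* is the full span between the two
outer points: default 30 mm longitudinally and $\pi/4$ rad
circumferentially, which on the validation phantoms resolve the peak
curvatures without spurious oscillation; these correspond roughly to the
vessel diameter and one eighth of the circumference, and should be
rescaled accordingly for vessels of very different caliber. Curvature is
an unsigned magnitude, reported in cm$^{-1}$ by default (a `units = "mm"`
flag switches to mm$^{-1}$). Nodes whose longitudinal window would leave
the $\sigma$ domain are masked rather than computed one-sided; collinear
stencils (area below $10^{-12} \times$ max side$^2$) return 0; coincident
stencil points are an error for the scalar operations and a masked node in
field computation. The product and mean of the two directional curvatures
are exposed as proxies for the Gaussian and mean curvature; they are
proxies only, since the directions are the coordinate directions, not
principal directions.

### Eccentricity

Cross-sectional eccentricity generalizes the ellipse formula to irregular
contours: scanning orientation $\varphi$ over $[0, \pi)$ (default step
$\pi/720$), each $\varphi$ yields the orthogonal pair of centroid chords;
the pair minimizing $d/D$ defines the major diameter $D$, minor $d$, and
$e = \sqrt{1 - d^2/D^2}$. Chords take the *farthest* boundary intersection
along each ray, so non-convex wiggles do not truncate a diameter (a
non-convexity warning is emitted). The orientation $\theta_e$ is the angle
between the major diameter and the Greenwich direction; a diameter is
undirected, so of the two representatives the one in $[0, \pi/2]$ is
reported (a major axis at $3\pi/4$ folds to $\pi/4$). For numerically
circular sections ($e < 10^{-6}$) the orientation is undefined and masked.
Spirality is the central finite difference of $\theta_e$ (unwrapped with
period $\pi$) with respect to $\sigma$.

## The software phantoms

Validation uses two generated phantoms whose geometry is known in closed
form; they are first-class, tested code, and their output files are
ordinary pipeline inputs.

**Simple phantom** — circular sections of radius 10 mm, two 60 mm straight
legs joined by a 90° bend of centerline radius 30 mm, so the inner and
outer surface tracks have 20 and 40 mm radius of curvature
(0.5 / 0.25 cm$^{-1}$) and every section reads 1.0 cm$^{-1}$
circumferentially. Contours every 5 mm (half the radius, mirroring how
clinical stacks are segmented), 96 points each, exactly orthogonal to the
analytic centerline. A 6 mm branch stub meets the proximal leg tangentially
with one exact point coincidence, so fiducial detection is well posed and
pins $\theta = 0$ to the inner side of the bend.

**Complex phantom** — elliptical sections (40 mm major / 20 mm minor
diameter, $e = \sqrt{3}/2 \approx 0.866$), two 90° bends in orthogonal
planes with the minor semi-axis (10 mm) in each bend plane. Bend 1 has
centerline radius 10 mm (outer surface track 20 mm radius, 0.5 cm$^{-1}$;
the inner track pinches to a point — see below) and bend 2 has 20 mm
(inner track 10 mm radius, 1.0 cm$^{-1}$). Between the bends the section
orientation rotates by $\pi/2$ through a transition centered 96 mm distal
to the branch contour. At the vertices the analytic circumferential
curvature is $a/b^2 = 2.0$ cm$^{-1}$ and on the flats $b/a^2 = 0.25$
cm$^{-1}$.

Design choices that were genuinely open:

* **Bend radii.** The source geometry prints surface-track curvatures, not
  centerline radii; the radii above are reconstructed from outer
  $0.5$ cm$^{-1}$ ($R_{c1} + 10 = 20$ mm) and inner $1.0$ cm$^{-1}$
  ($R_{c2} - 10 = 10$ mm). This reconstruction makes bend 1's inner
  surface radius exactly zero: the inner track pinches to a single point.
  The generator permits the tangent case (with a logged message) and
  errors only when the semi-axis exceeds the bend radius; the field
  computation masks the degenerate circle fits at the pinch.
* **The transition.** Implemented as a three-phase "twist through the
  circular throat": the section first blends to a circle with its
  orientation fixed, the full $\pi/2$ rotation happens while the section
  is circular, then the section blends back with the axes swapped
  (total length 10 mm, cosine ramps). The rationale is that a circle is
  the one shape with no defined orientation, so rotating there introduces
  no material ambiguity: snap-based Greenwich propagation cannot be
  dragged sideways by a rotating major axis. (A naive simultaneous
  morph-and-rotate lets the closest-point step fall inside the fat
  ellipse's evolute, where the nearest boundary point jumps off-axis and
  the distal orientation lands ~0.2 rad off; the phased twist reproduces
  the expected $\theta_e \approx 0$ distally.) The eccentricity profile
  dips to 0 in the throat and the orientation flips from $\pi/2$ to 0
  across it.
* **Windows vs. short bends.** Bend 1 spans only $\sim 15.7$ mm of
  centerline arc, so a 30 mm window cannot lie inside it; centered on the
  bend it averages bend with straights and reads $\sim 0.45$ cm$^{-1}$
  instead of 0.5 — a bias of the measurement protocol, not of the
  implementation. The validation therefore scores bend 1's outer track
  with a 10 mm window (all three points in-bend), and keeps the standard
  30 mm window for bend 2, whose 31.4 mm arc just accommodates it. This
  is the same rule as the package's general guidance: the window must not
  exceed the feature it measures.

What the phantoms do *not* emulate: segmentation noise (optional seeded
Gaussian jitter exists but is off by default, since the validation world
is noise-free), non-planar contours, non-orthogonal sections, branching
beyond a single fiducial stub, and longitudinally varying caliber. A green
phantom suite therefore establishes correctness of the geometry pipeline,
not robustness to segmentation artifacts.

## Numerical choices

* Interpolation in $\theta$ follows the contour polygon between the two
  bracketing boundary points — the interpolated point stays on the
  sampled surface. Radii interpolate linearly in $\theta$ then $\sigma$;
  both evaluations are exact at stored samples (tested to $10^{-9}$ mm).
* Whether $\theta$ between samples is polar angle or arc-length fraction
  is not fixed by the formulation; polar angle about the centroid was
  chosen, consistent with how the eccentricity orientation is defined.
  Handedness (right-handed about the distal tangent) was likewise chosen
  and is tested via the flipped-tangent case.
* Contour planes are least-squares fits (SVD); normals orient along the
  local proximal-to-distal direction.
* The fiducial "intersection" of two sampled surfaces is a proximity test;
  the default tolerance is half the mother contours' mean inter-point
  spacing.
* The eccentricity scan is exhaustive over the $\varphi$ grid rather than
  an optimizer: robust for irregular contours, no smoothness assumption,
  and a refinement-consistency property (a coarse scan never beats a 10x
  finer one by more than $10^{-6}$) is tested.
* All coordinates are mm internally; curvature converts to cm$^{-1}$ at
  the reporting boundary.

## Known limitations

Piecewise-linear centerlines and linear interpolation make results
sensitive to contour spacing and orthogonality; spline interpolation of
centerline and contours is out of scope. Curvature here is along
coordinate lines, not principal curvature from surface patches. The
coordinate system handles a single vessel with one anchoring bifurcation;
multi-branch coordinate systems are out of scope. Published error tables
for the original phantoms depend on an unpublished discretization and are
deliberately not asserted numerically; the property suites (circle-fit
oracle equivalence, exactness on circles, rigid-motion invariance, scale
covariance, closed-form ellipse eccentricity) play that role instead.
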