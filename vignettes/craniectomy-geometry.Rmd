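---
title: "Quantifying volume expansion after decompressive craniectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying volume expansion after decompressive craniectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniex)
```

## The question

A decompressive craniectomy (DC) removes part of the skull so a swollen
brain can expand outward. Two surgical levers control the gained space:
how much bone is removed (defect size) and how far the soft tissue can
bulge outward (contour elevation). `craniex` models both levers
geometrically — on reconstructed CT-like slice stacks and on an
idealized elliptical skull — and quantifies the resulting volume gain.

## The elliptical skull model

The axial skull cross-section at the defect level is the ellipse
$x^2/a^2 + y^2/b^2 = 1$, by default $a = 65$ mm along the defect axis
and $b = 75$ mm along the chord direction, a typical adult head. The
craniectomy is a chord perpendicular to the $x$-axis at distance $h$
from the centre; its length, the *tangential diameter*
$d = 2b\sqrt{1-h^2/a^2}$, is the proxy for craniectomy extent. The
elevated (bulged) contour over the defect is modelled as the upper half
of a new ellipse centred at the chord foot $(h, 0)$:

$$y_h(x) = b_h\sqrt{1 - \frac{(x-h)^2}{a_h^2}}, \qquad
  b_h = b\sqrt{1 - h^2/a^2}, \quad a_h = a + k - h,$$

so it meets the skull at the chord ends and extends $k$ mm beyond the
original vertex. The semi-axis $b_h$ is a *constant* of the new
ellipse: a formulation with $x$ in that factor would not describe a
point on the new ellipse and is undefined for $x > a$, while this form
reproduces the model's published behaviour; we therefore use it
throughout.

The first-quadrant area gain is
$\Delta A = \int_a^{a+k} y_h\,dx + \int_h^a (y_h - y)\,dx$, evaluated
by the rectangle rule with $n = 2000$ rectangles per integral — left
endpoints on $[a, a+k]$, right endpoints on $[h, a]$, matching the
summation limits of the original formulation — and doubled for both
quadrants. The volume-increasing rate divides $\Delta A$ by twice the
left-endpoint rectangle sum for the quarter-ellipse area and is
reported in percent. Sweeping $h$ over the grid $h_i = i\,a/500$
($i = 0,\dots,499$; a 0.13 mm step) gives the gain as a function of
$d$.

```{r plateau}
s <- sweep_tangent_diameters(k = 10, n_grid = 500, n_rect = 2000)
find_plateau(s)
```

The gain is not monotone in defect size: it peaks at $d \approx 143.6$
mm and then *declines* toward the maximal diameter $2b = 150$ mm. The
plateau drifts toward $2b$ as $k$ grows. Intuitively, a defect
approaching the midline forces the elevated ellipse to flatten
($b_h \to b$ while the overlap with the original ellipse grows), so the
marginal bone removal stops paying off.

### Numerical behaviour

The rectangle sums are compared in the test suite against the exact
ellipse-segment antiderivative
$F(u) = (u\sqrt{1-u^2} + \arcsin u)/2$, for which
$\Delta A = a_h b_h F(1) - ab\,[F(1) - F(h/a)]$. At $n = 2000$ the
one-sided endpoint error is below $10^{-3}$ relative over nearly the
whole $(h, k)$ domain; it is largest (about $2\times10^{-3}$) for
shallow elevations at $h \to 0$, where the right-endpoint sum works
against the vertical tangent of $y(x)$ at $x = a$ and $\Delta A$ itself
is smallest. The error shrinks as $1/n$. The degenerate chord $h = a$
yields exactly zero gain, with no division by the vanishing $b_h$.

### Maximal scalp elevation

The scalp can stretch only so far. If the defect-margin arc of length
$X$ can lengthen by at most $ext$ mm (default 4.1 mm), comparing the
coarse perimeter approximation $2\pi b + 4(a-b)$ of the original and
elevated ellipses gives the closed form

$$K = \frac{4\,ext\,a + (2\,ext\,\pi - 4\,ext)\,b}{X\,(2\pi - 4)}.$$

```{r scalpk}
X <- ellipse_perimeter_approx(75, 65, pi_const = 3.14) / 2
X
scalp_elevation_K(a_ap = 75, b_lat = 65, X = X, pi_const = 3.14)
```

Two conventions deserve note. First, the integration model uses
$a = 65$ (defect axis) and $b = 75$, while the elevation-height formula
is conventionally quoted with the anteroposterior semi-axis
$a_{ap} = 75$ first and the lateral $b_{lat} = 65$ second; the package
keeps the two parameter sets explicit and never swaps them silently.
Second, the formula's familiar constants (16.4, 9.348, 2.28) arise with
$\pi = 3.14$; `pi_const` defaults to exact $\pi$ and is set to 3.14
only to reproduce hand calculations. The tests also verify the formula
against an independent one-dimensional root finder on the
perimeter-ratio equation, to which it is algebraically equivalent for
any inputs.

## The slice pipeline

**Phantoms.** Real DC series cannot be redistributed, so the
`phantom_generator` builds synthetic CT-like stacks: elliptical bone
annuli (outer semi-axes following an ellipsoidal profile, default
$65 \times 75 \times 80$ mm, 6 mm bone) rasterized on a 512-pixel grid
over a 300 mm field of view (0.586 mm/pixel) with 1.25 mm slices,
emulating a clinical head CT matrix. A defect is an angular sector
removed from one lateral half over a slice range. Presets span the
three clinical defect-area groups used for reporting (< 125 cm²,
125–150 cm², ≥ 150 cm²): their sectors project to 78, 145 and 167 cm²,
inside the clinically observed 56–169 cm² range. The phantoms are
deliberately clean — no soft tissue, no Hounsfield noise, exact mirror
symmetry (optional seeded jitter exists for robustness checks) — so
passing tests demonstrate the geometry processing is correct, not that
the pipeline is robust to clinical artefacts such as asymmetric
anatomy, metal streaks or an imperfectly chosen symmetry axis.

**Outline extraction.** Skull cross-sections are star-shaped about
their centre, so the outline is traced by casting equiangular rays
(default 720, i.e. 0.5°) from the centre on the symmetry axis and
locating the sub-pixel 0.5 iso-level crossing of the bilinearly
interpolated mask along each ray. The radial parameterization makes the
mirror step exact: reflection across the axis maps ray $\theta$ to ray
$\pi - \theta$ on the same grid. Rays meeting no bone form the defect
gap. The two cut angles are then refined by bisection between the last
hit and first miss rays, and rays within one pixel's angle of a cut are
reassigned to the gap: their 0.5-crossing lies on the rasterized cut
face rather than the skull surface and would otherwise contaminate the
reconstruction by up to a couple of pixels.

**Mirror fill and elevation.** The gap is filled with the reflected
contralateral radii (the *regular* contour), tagged `reconstructed`.
For elevation $k$, the perpendicular bisector of the defect chord
$DD'$ meets the regular segment at $P$; the apex is $X = P + k$ along
the outward bisector, and the reconstructed segment becomes the unique
circular arc through $D$, $X$, $D'$ — the simplest curve through the
three defining points, degenerating to the chord as the sagitta
vanishes and falling back to the polyline $D\!-\!X\!-\!D'$ in the
collinear case. At $k = 0$ the arc passes through $P$, and its enclosed
area matches the regular contour within 1 % on the phantoms (an
arc-vs-ellipse discrepancy inherent to the choice of curve family,
which the source construction leaves open).

**Meshing.** Ring $L$ connects to ring $L+1$ by mapping point $m$ to
point $\lfloor m N_{L+1}/N_L \rfloor$, two triangles per point; the
map's rounding and the ring registration are not fixed by the source
construction, so the package floors the map and rotates each ring to
start at its most anterior point. Both triangles are wound consistently
outward (the raw vertex-set rule leaves orientation free, and an
alternating winding would corrupt signed volumes). The pipeline
resamples all rings to a common point count, which makes every stacked
band watertight; ends are closed with centroid fans. Volumes come from
the divergence theorem (signed tetrahedra); `enclosed_volume()` refuses
non-watertight input naming the open edges. Meshes round-trip through
Wavefront OBJ with `g original` / `g reconstructed` groups preserving
the flap labelling.

**Quantification.** The defect area is the shoelace area of the margin
polygon formed by the per-slice endpoints D/D′ projected on the
sagittal plane; volumes are measured over the standard elevation
schedule 0–30 mm by 2 and 35–50 mm by 5 (20 heights), and rates are
$(V_k - V_0)/V_0 \times 100$. The default model is bounded by the
outer skull surface (the "whole model" convention, bone shell
included, so baseline $V_0$ contains the shell); `boundary = "inner"`
bounds at the inner table instead, and whole-minus-inner approximates
the bone-shell volume, mirroring the whole-minus-bone decomposition
used to isolate brain tissue.

## Verification strategy and problem sizes

Every geometric result is checked against an independent oracle
computed in the test suite: rectangle sums against the ellipse-segment
closed form; the elevation-height formula against root finding; phantom
outlines, chords and projected areas against analytic ellipse geometry;
mesh volumes against closed-form solids (prisms, ellipsoids: the
$65\times75\times80$ phantom mesh is within 1 % of
$\tfrac{4}{3}\pi abc$) and against a brute-force voxel-counting
ray-cast oracle at 1 mm (within 2 %). Property tests cover contour
closure and simplicity, nesting of elevated contours, watertightness,
Euler characteristic 2, strict rate monotonicity over the 20-step
schedule, and the 125/150 cm² group boundaries.

The routine test runs use reduced sizes (96–256-pixel grids, 120–360
rays, coarse sweeps) chosen to exercise every code path at sub-pixel
tolerances; the acceptance-level checks run the model at its reference
sizes — 500-step sweeps with $n = 2000$ rectangles, and 512-pixel,
128-slice phantoms with 360–720 rays — where all reported quantities
are stable to well under the tolerances quoted above.

## Limitations

- Unilateral defects only: a bilateral DC leaves no intact
  contralateral template to mirror.
- The symmetry axis comes from metadata/configuration, not interactive
  picking; a mis-specified axis biases the fill by twice its offset at
  the apex.
- The elevated-contour curve family (circular arc) and the 3D stitching
  conventions are explicit package choices where the source
  construction is silent; both are validated by the $k = 0$ agreement
  and brute-force manifold checks, but other smooth interpolants would
  differ at the percent level.
- The elliptical model is a single axial section; no 3D ellipsoid
  integration is attempted, and patient-level statistics (mixed models
  on clinical cohorts) are out of scope — the per-model tables emitted
  here are suitable input for any external statistics package.
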