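---
title: "Quantifying nucleus and division-axis geometry in 3D spheroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleus and division-axis geometry in 3D spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidgeom)
```

## The measurement problem

Multicellular tumour spheroids are dense, roughly spherical aggregates a few
hundred micrometres across. Light-sheet fluorescence microscopy (LSFM) of
optically cleared, nuclear-stained spheroids produces z-stacks in which
individual nuclei are visible throughout the volume, but fully automatic
voxel-level segmentation of thousands of tightly packed nuclei is not
reliable at this image quality. The tractable alternative implemented here
is semi-supervised: a human delimits a handful of points on each nucleus
boundary in three orthogonal section views, and everything downstream is
computed from those points plus the raw stack.

Three questions drive the design:

1. **How elongated is each nucleus?** A nucleus is modelled as an ellipsoid
   with centre $c$, orthonormal axes $e_1, e_2, e_3$ and semi-axis lengths
   $L_1 \ge L_2 \ge L_3$. Elongation is the aspect ratio $L_1/L_3$ (1 for a
   sphere). A nucleus counts as *elongated* when $L_1/L_3 > 1.5$, strictly.
2. **How is it oriented relative to the tissue surface?** The spheroid
   surface is approximated by the convex hull of the thresholded volume; the
   orientation of a nucleus is the acute angle between its long axis $e_1$
   and the outward normal at the hull point nearest to $c$. By this
   convention 90° means parallel to the surface, 0° means radial.
3. **Where does the cell division axis point, and how long do mitotic
   phases last?** The metaphase plate is a flattened ellipsoid; its shortest
   axis $e_3$ is the division axis, measured with the same angle convention
   against the hull. Phase durations come from annotated time-lapse frames:
   prometaphase is condensation → plate, metaphase is plate → anaphase.

## Ellipsoid fitting

The fit is algebraic least squares on the general quadric

$$a x^2 + b y^2 + c z^2 + d xy + e xz + f yz + g x + h y + i z + j = 0,$$

minimising $\sum_i Q(p_i)^2$ over coefficient vectors of unit Euclidean
norm. The minimiser is the right singular vector of the $n \times 10$ design
matrix belonging to the smallest singular value. The quadric is then
decomposed: the centre solves $\nabla Q = 0$, and the eigendecomposition of
the quadratic form, normalised at the centre, yields axes and lengths. If
that form is not positive definite the input did not determine an ellipsoid
and the fit fails loudly rather than returning a hyperboloid in disguise.

Properties that motivated this choice over an iteratively constrained
solver:

* it is **exact on noiseless data** — points in general position on a true
  ellipsoid are recovered to numerical precision, which gives the test
  suite a sharp oracle;
* it is **equivariant**: rotating or translating the annotation points
  rotates/translates the fit, with lengths unchanged;
* it is cheap and has no convergence parameters. The residual being
  minimised is documented, so a geometrically weighted solver could be
  swapped in without changing the interface.

Points are centred and scaled to unit RMS radius before building the design
matrix; this conditioning step is what keeps recovery near machine
precision for centres far from the origin.

A quadric has nine degrees of freedom after normalisation, so at least nine
points are required; the tri-view annotation of eight points per view
provides 24. View tags (`xy`, `yz`, `xz`) are carried as metadata only —
all points enter one joint 3D fit.

**Degenerate orientation.** When $L_1/L_2 < 1.02$ the long axis of a
near-oblate or near-spherical nucleus is numerically meaningless. Such fits
are flagged `orientation_reliable = FALSE`; they keep contributing to
aspect-ratio statistics but are excluded from angle statistics.

## Surface extraction

The envelope pipeline is deliberately simple: Gaussian denoising, a global
threshold, then the convex hull of all foreground voxel centres in physical
micrometre coordinates.

* **Denoising** is a separable Gaussian with one physical width
  `sigma_um` (default 2 µm); the per-axis sigma in voxels is
  `sigma_um / spacing`, so anisotropic stacks (1 µm z-step, ~0.65 µm
  pixels) are smoothed isotropically in physical space. Outside the stack
  the image is taken as zero.
* **Thresholding** defaults to Otsu's criterion on a 256-bin histogram of
  the full 3D volume; a fixed level is available for phantoms and for
  stacks whose histogram is not bimodal. Foreground is *strictly greater*
  than the threshold. A warning is emitted when the foreground fraction is
  implausibly small, since uneven staining can defeat envelope extraction;
  the warning threshold is configurable.
* **Hulling** uses a quickhull implementation in C++ (no R package in the
  dependency set provides 3D hulls). Interior voxels cannot be hull
  vertices, so the mask is first thinned to its 6-connectivity boundary;
  hulls of half a million boundary voxels are routine. Every foreground
  voxel centre ends on the non-positive side of every face plane within
  10⁻⁹ µm. No morphological cleanup is applied by default (an optional
  largest-connected-component filter exists for noisy stacks).

Depth below the surface is the distance from a point to the nearest point
of the hull mesh, computed by exhaustive minimisation of the
point-to-triangle distance over all faces (vectorised across faces; ties
between equidistant faces break to the lowest face index). The outward
normal used for angles is the face normal of the nearest face — the mesh
is convex and faceted finely enough that interpolated vertex normals would
change angles by well under a degree, so the simpler convention is
adopted.

## Orientation and division-axis records

`nucleus_orientation()` combines the two halves: depth of the ellipsoid
centre (the centre, not the nucleus surface, matching how the annotation
centre projects onto the envelope) and the angle of $e_1$ to the local
normal. Centres more than a configurable distance (default 5 µm) outside
the hull indicate mismatched annotation/stack pairs and raise an error;
centres marginally outside (facet sag of a coarse mesh) count as depth 0.

The cohort summary reports type-7 quartiles of the aspect ratio over all
records, the elongated fraction under the strict 1.5 criterion, and angle
quartiles over the *elongated and orientation-reliable* subset only.
The depth shell filter is inclusive on both bounds; the default 0–100 µm
shell captures the peripheral layers where confinement acts.

For division axes, the reference plate of each tracked mitosis is the last
plate detected *strictly before* anaphase onset; when anaphase was never
observed the last available plate is used and flagged. The plate must be
genuinely flattened ($L_2/L_3 > 1.1$ by default) for its shortest axis to
be trusted.

## Mitosis timing

Events are annotated as frame indices (condensation, plate establishment,
anaphase onset) at a frame interval of 4 minutes by default. Durations are
therefore non-negative multiples of the interval. Censoring is handled
explicitly:

* condensation before the first recorded frame → the prometaphase value is
  a lower bound (flagged, excluded from means);
* plate never observed → lower bound to the last recorded frame, metaphase
  duration absent;
* anaphase never observed → the metaphase duration is a lower bound.

The long-prometaphase fraction (cutoff 40 min) counts a cell as long when
its observed duration *or* its lower bound exceeds the cutoff; lower-bound
cells whose bound does not reach the cutoff are indeterminate and are
excluded from the denominator and reported separately. Cohort means use
the sample (n−1) standard deviation over fully monitored cells.

## The synthetic phantom

No imaging data ship with the package, so every pipeline stage is
validated against a generator whose ground truth is known exactly. The
phantom emulates the acquisition geometry: a ball of default radius 325 µm
(a 650 µm spheroid), voxel spacing (1, 0.65, 0.65) µm — the z-step from
the acquisition protocol, the xy pixel size typical of a 10x objective and
otherwise arbitrary — containing non-overlapping ellipsoidal nuclei.

Generator defaults were fixed once, as plausible study conditions:

| parameter | default | rationale |
|---|---|---|
| aspect ratio | $1 + \mathrm{Lognormal}(\log 0.83,\ 0.4)$ | median 1.83, the elongation scale reported for peripheral spheroid nuclei |
| $L_3$ | 3 µm | HCT116-like nuclear minor radius |
| orientation | tangential ± 10° | the observed preferential alignment |
| intensities | 10 / 40 / 200 | background / cytoplasm / nucleus grey levels |
| noise | Poisson shot + Gaussian read (sd 2) | generic camera model |
| attenuation | 0.002 µm⁻¹ | mild residual depth loss after clearing |
| PSF | Gaussian, 1 µm | order of an LSFM point-spread function |

Orientation modes: *tangential* draws $e_1$ in the local tangent plane,
*radial* along the centre-to-nucleus direction, *isotropic* uniformly on
the sphere; a Gaussian angular perturbation is then applied. The isotropic
mode supplies an analytic null: for an isotropic axis the cosine of the
angle to any fixed direction is uniform on [0, 1], so the median angle is
exactly 60° — a useful calibration that involves no imaging at all.
Annotations are sampled on the intersection ellipses of each nucleus with
the three coordinate planes through its centre, mimicking tri-view
clicking, with isotropic jitter (2 % of $L_3$ in the validation suite).
Mitosis events draw phase durations from normal distributions truncated
below at 4 min (one frame) and discretise them to frames; condensation
times are uniform over a window extending one mean prometaphase before the
recording, so both censoring mechanisms occur at realistic rates.

Everything is deterministic given the spec seed; rendering, plate and
event generation derive fixed offsets from it so stages can be re-run
independently.

**What the phantom does not emulate** — and hence what passing tests do
not establish about real data: light-sheet stripe artefacts and scattering,
spatially varying staining, nucleus shape irregularity (real nuclei are
not exact ellipsoids), human click bias (jitter is isotropic and
unbiased), cell crowding and gel mechanics. The `"capped"` shape option
flattens one pole to exercise non-spherical hulls, but it is a geometric
device, not a mechanical model of agarose confinement.

## Numerical choices and edge cases

* All geometry lives in physical µm; voxel-to-µm conversion happens at
  I/O only.
* Quickhull treats points within 10⁻⁹ µm of a face plane as on the hull;
  lattice data (voxel centres) contain many exactly coplanar points and
  are handled by the global visible-set search rather than a local
  breadth-first walk, which the near-coplanar faces would break.
* Angles are reported in degrees in [0, 90]; axis comparisons use
  $\arccos |u \cdot n|$, so every axis is a line, never an arrow, and sign
  flips anywhere in the pipeline are harmless.
* Collinear triangles, coplanar annotation sets, indefinite quadrics,
  empty cohorts, flat images under Otsu, and plates without a pre-anaphase
  reference all raise distinct, early errors.
* Mann-Whitney switches from the exact null distribution to the
  tie-corrected normal approximation with continuity correction when
  either sample exceeds 8 observations or ties are present; the method
  used is recorded in the result object. Boxplot summaries use type-7
  quartiles and Tukey 1.5 × IQR whiskers.

## Validation problem sizes

The shipped validation suite exercises: exact recovery on 100 random
ellipsoids; surface queries on 50 random hulls (20–200 points, 1000
queries in total) against a per-face scalar oracle; orientation nulls with
2000 isotropic and 300 tangential/radial nuclei; one fully rendered
phantom at radius 150 µm with 150 nuclei (≈ 6 × 10⁷ voxels) pushed through
denoise → threshold → hull → fit → orientation; timing cohorts of 500
cells at two parameter sets compared with a quadrature oracle for the
truncated-normal mean; and exhaustive Mann-Whitney enumeration for all
sample sizes up to 6. These sizes were chosen so the whole suite completes
in a few minutes on one CPU while keeping Monte-Carlo tolerances honest
(the 2° band on the isotropic median corresponds to roughly 2.7 standard
errors at n = 2000).

## Known limitations

* The convex hull is a one-sided surface estimate: it bridges concavities,
  so depths are underestimated wherever a real spheroid is dented.
* Aspect ratios from algebraic fits are slightly biased for very noisy
  annotations; at the 2 % jitter level this bias is far below the 5 %
  validation band, but heavier-handed annotation would warrant a
  geometric-distance refit.
* The elongated fraction depends on whether it is computed inside or
  outside the depth shell; `summarize_orientation()` operates on whatever
  record set it is given, so both variants are one `shell_filter()` call
  apart — users comparing cohorts should fix one convention.
* Anaphase duration is out of scope: its endpoint (decondensation onset)
  is not reliably annotatable in this kind of data.
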