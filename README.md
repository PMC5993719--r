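# spheroidgeom

Quantitative 3D geometry of cell nuclei and cell divisions in multicellular
tumour spheroids imaged by light-sheet fluorescence microscopy (LSFM).

Spheroids are dense, ~650 µm aggregates used as in-vitro tumour
micro-domains. In cleared, nuclear-stained stacks the interesting biology is
geometric: peripheral nuclei are elongated and lie parallel to the spheroid
surface, cell divisions orient the same way, and physical confinement (for
example growth in agarose) degrades both and delays prometaphase. This
package implements the measurement pipeline behind those statements, for
image analysts who have LSFM z-stacks and per-nucleus boundary annotations
rather than full automatic segmentations.

## What it computes

Each nucleus is an ellipsoid with centre *c*, orthonormal axes *e1, e2, e3*
and semi-axis lengths *L1 ≥ L2 ≥ L3* (µm), fitted to manually delimited
boundary points from three orthogonal views by algebraic least squares: the
quadric coefficient vector minimising Σᵢ Q(pᵢ)² under a unit-norm
constraint (smallest right singular vector of the design matrix), decomposed
into centre/axes/lengths with an explicit ellipsoid-validity check.

* **Elongation**: aspect ratio L1/L3; a nucleus is *elongated* when
  L1/L3 > 1.5 (strict).
* **Surface**: the spheroid envelope is the triangulated convex hull of the
  Gaussian-denoised, thresholded (Otsu by default) stack, in physical µm.
* **Orientation**: angle between e1 and the outward normal at the hull
  point nearest to *c*, in [0°, 90°]; 90° means parallel to the surface.
  Summaries use the 0–100 µm depth shell and the elongated subset.
* **Division axis**: shortest axis of the flattened metaphase-plate
  ellipsoid (last plate strictly before anaphase onset), same angle
  convention.
* **Mitosis timing**: prometaphase (condensation → plate) and metaphase
  (plate → anaphase) durations from 4-min time-lapse frames, with explicit
  lower-bound handling for censored cells, cohort means/SDs, the
  long-prometaphase (>40 min) fraction, and Mann-Whitney comparisons
  between conditions.
* **Synthetic phantoms**: ground-truthed spheroids (nuclei with controlled
  aspect ratio and tangential/radial/isotropic orientation, rendered
  voxel stacks with PSF blur, Poisson/Gaussian noise and depth
  attenuation, annotation sets, mitosis event tables), deterministic per
  seed, so the whole pipeline is testable without microscope data.

## Worked example

Simulate a small spheroid phantom, run the full pipeline, and summarize:

```r
library(spheroidgeom)

spec <- phantom_spec(n_nuclei = 40, spheroid_radius = 60, seed = 2)
gt   <- generate_ground_truth(spec)           # true ellipsoids + sphere
vol  <- render_volume(gt)                     # noisy voxel stack
hull <- extract_convex_hull(binarize(denoise(vol, 2)))
hull
#> triangle_mesh: 8510 vertices, 17016 faces
#>   extent (um): x [8.45, 127.40]  y [8.45, 127.40]  z [9.00, 127.00]
#>   enclosed volume: 895219.5 um^3

# annotation -> fit round trip (2% click jitter), then orientation records
fits <- lapply(seq_along(gt$nuclei), function(i)
  fit_ellipsoid(sample_annotations(gt$nuclei[[i]], 8,
                                   jitter_sd = 0.02 * gt$nuclei[[i]]$lengths[3],
                                   seed = 100 + i)))
names(fits) <- names(gt$nuclei)
fits[[1]]
#> ellipsoid: centre (39.366, 100.559, 56.715) um
#>   semi-axes L1=4.671 L2=3.696 L3=2.995 um  (aspect ratio 1.560)

rec <- shell_filter(orientation_records(fits, hull), 0, 100)
s   <- summarize_orientation(rec)
#> n = 40 nuclei; median L1/L3 = 1.88 [Q1 1.70, Q3 2.14]
#> elongated fraction = 90%; median angle (elongated) = 84.3 deg
```

The median angle near 90° recovers the tangential orientation the phantom
was built with (the generator default draws long axes in the local tangent
plane ± 10°); an isotropic phantom instead gives the analytic null median
of 60°.

Timing, on a simulated 104-cell cohort at the control parameters:

```r
d <- phase_durations(generate_mitosis_events(104, seed = 3))
cohort_summary(d)
#> prometaphase 15.5 +/- 6.1 min (n = 94); metaphase 13.2 +/- 4.0 min (n = 88)
long_prometaphase_fraction(d)
#> long prometaphase (>40 min): 1.1% of 95 determinate cells
```

A command-line front end with `simulate` / `fit` / `hull` / `orient` /
`divide` / `timing` / `compare` subcommands is installed at
`inst/cli/spheroidgeom.R`; it reads/writes CSV, multi-page TIFF, ASCII PLY
and JSON.

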