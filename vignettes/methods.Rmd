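---
title: "Models and methods behind devbrainmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind devbrainmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(devbrainmap)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the choices made where the design was open,
and what the synthetic phantom does and does not establish about real
data.

## Coordinate and counting conventions

All volumes are (x, y, z) arrays with physical spacing in micrometres; z
is the sectioning axis (50 µm steps at the working resolution, 20 µm in
plane). Physical coordinates have their origin at the corner of the first
voxel, and a point with coordinate c on an axis with spacing s belongs to
voxel `floor(c/s) + 1`: voxel intervals are half-open, so a cell sitting
exactly on a boundary plane is assigned to the higher-index voxel. This
one rule removes every ambiguity in cell-to-region assignment at region
borders. Mirroring, used by the symmetry score, is always about the mid-x
plane.

Cells are counted on sparse 2D sections; the 3D estimate multiplies the
2D count by the conversion factor k3D = 1.4. The factor is applied to
per-region sums, not per cell — equivalent by linearity, and it keeps
integer 2D counts inspectable. Regional volumes are voxel counts times
the physical voxel volume (20 × 20 × 50 µm³ = 20 000 µm³), and densities
are n3D divided by the regional volume in mm³. Parent regions in the
ontology aggregate *summed* counts and *summed* volumes; recomputing the
parent density from those sums (never averaging child densities) is what
makes `density × volume = n3d` hold at every node. Cells falling in
background voxels or outside the grid are retained and flagged, excluded
from regional counts, and reported as attributes — how such cells were
handled upstream is not derivable from the data, so the package makes its
own handling explicit and auditable.

## Registration

`register()` is intensity-based multi-resolution registration: a 3D
affine stage over a 4-level pyramid, then a 3D cubic-B-spline free-form
stage over a 6-level pyramid with a coarse-to-fine control lattice
(starting at a third of the fixed extent, halved per level, floored at
two voxels). Both stages are optimized with analytic gradients — BFGS for
the 12 affine parameters, L-BFGS-B for the control-point displacements —
and are deterministic given inputs, configuration and seed.

Several numerical choices matter and were each validated against phantom
ground truth:

- **Multi-resolution by smoothing, not decimation of one side.** Each
  level Gaussian-smooths *both* images at the same physical scale in
  their own grids and decimates only the sample grid. Smoothing one image
  while point-sampling the other biases the metric, and the deformable
  stage will happily "explain" that bias with a spurious field of tens of
  micrometres. The moving image's smoothing scale is additionally matched
  through the current affine, since a fixed-space kernel corresponds to
  an affine-scaled kernel in moving space.
- **Gain/offset-invariant metric.** The default `"ncc"` metric profiles
  out the optimal global intensity gain and offset inside every
  evaluation before squaring residuals (the least-squares profile of a
  normalized-correlation metric; by the envelope theorem the spatial
  gradient is simply scaled by the fitted gain). Normalizing the two
  volumes once up front is not enough: any change in the
  foreground/background mix — a younger, smaller brain in the same field
  of view — shifts the global moments and leaves an intensity mismatch
  that a free deformation field would otherwise absorb geometrically.
  `"mse"` on raw intensities remains available for strictly
  same-modality problems. A mutual-information metric is not implemented:
  all in-package use is same-modality, and the gain/offset-invariant
  metric covers the acquisition differences the averaging pipeline
  normalizes anyway.
- **Mask continuity.** Samples mapping outside the moving volume are
  excluded from the metric. The valid band extends half a voxel beyond
  the outermost voxel centres with edge-clamped interpolation (gradients
  zeroed in clamped directions), because two grids of identical extent
  would otherwise place every boundary sample exactly on the mask edge,
  making the metric discontinuous at the identity and killing the line
  search.
- **Composed optimization.** The B-spline stage optimizes
  `M(A(x + u(x)) + t)` directly, with the chain rule through the affine,
  rather than matching against an affinely-resampled intermediate volume.
  This avoids a second interpolation and keeps out-of-volume masking
  consistent with the final composite transform.

Transforms are ordered stage lists storing the resampling map (fixed →
moving). `apply_to_volume()` uses it directly; `apply_to_points()`
applies the inverse so that image content and point sets move together
(tested by warping an impulse image and its point into the same voxel).
Label resampling is nearest-neighbour only, which guarantees no label
absent from the input can appear. The B-spline inverse is computed on the
fly by fixed-point iteration with a tolerance of a tenth of a voxel.
Convergence is reported per level as a metric trace; a level ending above
its starting value triggers a warning carrying the trace.

## Templates and label propagation

`build_template()` registers every subject to a chosen reference —
`symmetry_score()` (the correlation between a volume and its mid-x
mirror) formalizes "pick the best left–right symmetric brain"; no
threshold is imposed, ranking is the use case — rescales each registered
subject to its 1st–99th percentile range (robust to acquisition gain
differences; the scheme itself is a package choice, as averaging requires
*some* normalization), and takes the voxelwise mean on the reference
grid. One pass only: no iterative template refinement, matching the
procedure the template construction emulates.

`propagate_labels()` carries a label volume from a source template to a
target through one registration, or through two composed registrations
when an intermediate-age template is supplied. The sequential route
exists because one-shot registration degrades as the morphological gap
grows; on phantoms with a large cumulative age deformation the direct
route visibly fails while two smaller hops survive — the acceptance suite
scores exactly this contrast via per-region Dice against ground-truth
labels.

## The phantom

The phantom is a first-class module, not a fixture: an ellipsoidal brain
whose dorsal shell is a six-layer cortex, an interior subcortex holding a
5 × 5 × 2 grid of box nuclei (50 by default), some interior voxels
labeled directly at the subcortex parent to exercise non-leaf
aggregation, and a three-level ontology. Intensity combines a radial
profile, anisotropic sinusoidal texture, per-layer contrast and distinct
per-nucleus brightness — the anatomical contrast registration needs to
pin down correspondence; mirrored nuclei share offsets so the volume
stays exactly mirror-symmetric at asymmetry 0. Subject and age-series
volumes are generated by evaluating these *analytic* fields at warped
coordinates rather than interpolating a base array: interpolation
attenuates fine texture nonuniformly and would bias registration tests
against the registrator.

Age structure is cumulative: each age adds a fresh smooth B-spline
increment (default 60 µm at the control points) on top of the previous
age's deformation plus a global scale (default 1, 0.92, 0.84, …), so
age-adjacent shapes are closer than age-distant ones — the geometric fact
that makes sequential propagation sensible. Per-subject variability is a
separate smooth random deformation (default 40 µm). All randomness
derives from one seed via a documented stream rule
(`seed + 1000·age + subject`), restored after use.

Cell counts per region are negative binomial with mean density × volume
and dispersion (NB `size`) θ. The defaults are the package's study
conditions, chosen once on realism grounds: θ = 20, i.e. ~22%
between-subject coefficient of variation, typical of regional cell counts
across littermates; and densities scaled so per-region *expected counts*
land in the realistic hundreds-to-thousands range despite the phantom's
miniature (~0.4 mm³) volume — in a scaled-down brain it is the counts,
not the densities, that preserve the statistical problem. The thinning
helper keeps each true 3D cell with probability 1/1.4, so the package's
×1.4 correction exactly inverts the phantom's 2D-count emulation in
expectation, making the conversion factor testable as an inverse pair.

What the phantom does *not* emulate: microscope point-spread and noise,
stitching artifacts, autofluorescence gradients, detector errors, and
real anatomical shape statistics. Passing tests therefore demonstrate the
correctness of the computation under the stated geometric and statistical
model — not detector robustness or atlas-quality registration on real
tissue.

## Count statistics

`nb_group_test()` fits `count ~ group + offset(log volume)` with a log
link and tests the group coefficient (the log fold change of density).
The exact test form was an open choice, settled by calibration at the
design's own sample size: with five subjects per group, both the NB Wald
z and the NB likelihood-ratio test (dispersion estimated per region by
maximum likelihood) reject far above nominal, violating the type-I
calibration the package requires of itself. The default `"quasi"` test —
a Wald t with quasi-likelihood (Pearson) overdispersion and n − 2 degrees
of freedom — holds the nominal level across the mean/dispersion ranges
the phantom spans, and is what the acceptance suite certifies over 2000
null cohorts. `"wald"` and `"lrt"` remain available. Degenerate all-zero
regions are flagged, given p = 1 by convention, and excluded from the FDR
family so untestable hypotheses do not dilute the correction.

`compare_groups()` additionally moderates the per-region quasi
dispersions across regions by empirical Bayes (limma's `squeezeVar`),
adding the prior degrees of freedom to the Wald t — the standard remedy
for the power loss of estimating a dispersion from ten observations, and
the reason a planted twofold effect is detectable at FDR < 0.05 with five
subjects per group at all. Multiplicity is controlled with the
Benjamini–Hochberg step-up procedure (`stats::p.adjust`; the test suite
checks it against a brute-force step-up oracle over grids of p-vectors).

The power machinery interprets the assumed effect size (default 0.85) as
a *log* fold change, i.e. a rate ratio of about 2.3. Interpreted as a
Cohen's d it would imply hopeless power at N = 5, contradicting the
design expectation that most regions reach 80% power; on the log scale
the expectation is reproduced for realistic means and dispersions. The
value is configuration, not hard-coded semantics. One caveat computed by
the acceptance suite deserves note here: requiring *zero* false positives
among ~48 null regions per replicate caps the joint success probability
of the planted-dimorphism experiment near `(1 − q·r/m)^(m−r)` even for a
perfectly calibrated test, so detection-with-zero-FP rates in the 70–90%
range are the expected behaviour of a correct implementation, not a
defect.

Histology helpers: `colocalization_percent()` is 100 × double-positive /
total positive, rounded to the requested decimals;
`puncta_positive()` exposes both the "more than" and "at least"
comparators for the puncta threshold (default ≥ 4) because both
conventions occur and neither is guessed as intent;
`spine_density_test()` reports spines per 10 µm of dendrite and compares
groups with the two-tailed pooled-variance (equal-variance) Student's
t-test.

## Flatmaps

The phantom's cortical flatmap parameterizes the dorsal shell by azimuth
and polar angle about the brain centroid and bins it into an 8 × 6 grid
by default — a stand-in for a precomputed cortical flattening, which this
package deliberately does not re-derive. Layer restriction intersects bin
voxels with the layer masks: layers 1–3 for the superficial map, layers
5–6 for the deep map; layer 4 belongs to neither restricted map while the
full-cortex map includes it (whether the deepest sublayer belongs with
"layer 6" is resolvable by passing explicit layer ids). Empty
intersections keep their bins with zero voxels and report density as
missing, never zero, and the renderer draws missing bins in a distinct
colour.

Bin "area" is interpreted as voxel measure (mm³): bins are voxel sets,
and using volume keeps count/volume/density identities exact. Per-age bin
volumes are obtained by warping the reference bin volume onto the age
grid through the supplied transform (the reverse registration of the
reference onto that age) and counting voxels there; a missing age
transform is an error rather than a silent fall-back to reference-age
volumes.

## Problem sizes and tolerances

The default phantom grid is 48 × 48 × 28 voxels at 20 × 20 × 50 µm —
large enough for six-level pyramids and fifty nuclei, small enough that a
full affine+B-spline registration takes about a minute on one CPU; the
test and acceptance suites use it throughout, with 2000 null cohorts for
type-I calibration, 100 replicate cohorts for the dimorphism experiment,
and 10-subject cohorts for density recovery. B-spline inversion tolerance
is 0.1 voxel; optimizer caps default to 80 (affine) and 60 (B-spline)
iterations per level; the L2 control-point penalty (1e−6) only breaks
ties in featureless regions.

## Known limitations

Registration accuracy is phantom-certified to roughly half a voxel for
deformations up to a few voxels; much larger single-hop deformations can
fail outright (which is precisely when the sequential route is needed).
The flatmap parameterization is angular, not geodesic, and is not meant
to reproduce any published flattening. The detector
(`detect_cells_2d()`) is a deliberate plumbing stand-in — threshold plus
connected components — behind the same cell-table interface a trained
detector would use. The NB machinery assumes counts are exchangeable
across subjects within group; batch structure and covariates beyond the
volume offset are out of scope.
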