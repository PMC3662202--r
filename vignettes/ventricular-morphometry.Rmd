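---
title: "Ventricular morphometry and AD/MCI classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventricular morphometry and AD/MCI classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventmorph)
```

# The problem

Cerebral atrophy in mild cognitive impairment (MCI) and Alzheimer's
disease (AD) shrinks gray and white matter and enlarges the CSF-filled
lateral ventricles. Because the ventricles are high-contrast on
T1-weighted MRI and easy to segment reliably, ventricular size and
shape are attractive markers for separating AD and MCI patients from
normal controls (NC). `ventmorph` implements a full marker-extraction
and classification chain for this setting, together with a synthetic
phantom generator so that every stage is testable without clinical
data.

This vignette is the package's methods reference: the models, each
tunable parameter with its default and rationale, the numerical
choices, and the limits of what the synthetic experiments demonstrate.

# Tissue segmentation and volumetry

Voxel intensities inside the brain are modelled as a three-component
Gaussian mixture; components are relabelled post hoc by ascending mean
to CSF < GM < WM (the T1 ordering). `fit_tissue_gmm()` runs EM with:

* **Initialization**: a k-quantile split of the in-brain intensities
  (deterministic; an explicit `init_means` override exists and the
  result is invariant to its order because of the mean sorting).
* **Convergence**: change in mean log-likelihood below `1e-6`, at most
  500 iterations. The log-likelihood is nondecreasing by construction
  and is exposed for inspection.
* **Variance floor**: `(1e-4 x intensity range)^2`, which keeps the
  noise-free (perfectly separable) case well defined; posteriors then
  collapse to exact 0/1 indicators in double precision.

Volumes use the counting rule: a voxel contributes its physical volume
to tissue *t* when the posterior for *t* exceeds 0.5; the whole-brain
volume thresholds the combined gray-or-white posterior. No spatial
priors, bias-field model or skull stripping are included: phantoms are
generated pre-aligned with zero background, and spatial normalization
of real data is expressly out of scope.

# Ventricle extraction

`extract_ventricle()` implements double-threshold region growing:

* **Band**: `[T_low, T_high]` defaults to the fitted CSF mean +/- 2 CSF
  standard deviations. This accepts ~95% of cavity voxels under
  Gaussian noise while excluding GM by a wide margin (the GM mean sits
  several CSF standard deviations above the band).
* **Seed region**: the largest 6-connected component of the eroded
  high-CSF posterior (`p_csf > 0.5` eroded by one voxel). Erosion
  removes the thin peripheral CSF sheet, so the surviving component is
  the cavity interior; growing from the whole region (rather than a
  single voxel) keeps both lateral lobes even when noise breaks the
  band's connectivity at the narrow midline. A manual seed override
  exists.
* **Connectivity**: 6-neighborhood for growing and labeling —
  conservative, avoiding leakage through diagonal noise bridges.
* **Morphology**: opening then closing with the 6-connected radius-1
  element. The opening removes noise-attached filaments; the closing
  fills interior voxels that fell outside the band. The kernel is the
  smallest symmetric 3D element; anything larger would erase genuine
  horn structure at routine voxel sizes.
* **Component keeping**: after morphology, the connected component(s)
  containing the seed region; if morphology removed every seed voxel,
  the component with the greatest overlap with the grown region.

Boundary maps use the 3x3 Sobel operator per axial slice with zero
padding, marking mask pixels with nonzero gradient magnitude — the
one-pixel boundary ring. Ventricular volume is the voxel count of the
mask times the voxel volume.

# Shape features

## 3D: probability maps and the matching coefficient

For each group, the probability map is the voxelwise mean of the
binary training masks; the discriminate map subtracts the control map
from a patient map, and a test subject's matching coefficient is the
plain inner product of its mask with the discriminate map. Inside
cross-validation the maps are rebuilt per fold, and each *training*
subject's own coefficient is computed against maps excluding that
subject, so no mask ever scores against a template it helped build.
The matching-coefficient columns are computed on request
(`feature_sets = "mc"`) but are not part of the default 17-descriptor
shape set, whose published count matches the 2D list alone.

## 2D: seventeen datum-slice descriptors

Descriptors are measured on the *datum slice* — the axial slice with
maximal ventricular cross-section (ties to the lowest index) — with
these conventions, fixed here because verbal definitions alone do not
determine them:

* **Area** = pixel count x pixel area; the four sub-areas split the
  region at the centroid G along the image axes (posterior/frontal x
  right/left) and sum exactly to the total.
* **Perimeter** = length of the traced outer contour of every
  connected component (Moore neighbor tracing; diagonal steps weigh
  `sqrt(2)`). Pure edge counting would overestimate smooth boundaries.
* **Circularity** = `100 * 4 * pi * Area / Perimeter^2`, the percent of
  a perfect circle. On published elderly control values (area ~1792
  mm^2, perimeter ~227 mm) this form lands near the reported ~45%.
* **Elongation** = major/minor axis ratio of the second-moment
  (inertia-equivalent) ellipse, including the 1/12 per-pixel term so a
  solid a x b rectangle yields exactly a/b.
* **Rectangularity** = area over the minimum-area oriented bounding
  rectangle of the pixel corners, searched in 1-degree steps; bounded
  by 1 with equality for axis-aligned rectangles.
* **Landmarks**: G is the centroid; A, B, C, D are the anterior-,
  right-, posterior- and left-most boundary pixels, with deterministic
  clockwise tie-breaking; distances are Euclidean in mm.
* **Minimum thickness** = minimum caliper (projection) width over 180
  orientations of the pixel-corner set.
* **Mean signature** = mean centroid-to-boundary-pixel distance (the
  centroid-distance shape signature).

Bilateral regions are measured as their union. Degenerate single-pixel
regions return distances 0, elongation 1 and circularity 100 by
convention. The suite verifies closed-form fixtures (square,
rectangle, disk), exact scale equivariance, and invariance under
90-degree rotation with mirror-swapping of the lateral sub-areas.

# Feature reduction

* **Mann-Whitney screening** (Route I) uses combined midranks,
  `U_obt = min(U1, U2)`, and the plain large-sample normal deviate
  with *no* tie correction and *no* continuity correction — exactly
  the printed large-sample form, whose calibration at the study's
  group sizes (17 vs 18) the acceptance suite measures at 0.046-0.05
  empirical type-I error. Two-sided p-values; features with p < 0.05
  survive. Each classification task filters on its own contrast; the
  three-class task keeps features significant in either
  patient-vs-control contrast. In folds too small to define a contrast
  (fewer than two training subjects in a group) screening is skipped
  rather than fabricated.
* **PCA** (Route II) standardizes features and eigendecomposes the
  correlation matrix, retaining the smallest leading set of components
  whose cumulative explained proportion reaches 95%. Eigenvector signs
  are fixed so each component's largest-magnitude loading is positive,
  making scores reproducible. Applied to the published per-component
  proportions, the rule retains 2 (volume), 8 (shape) and 6
  (volume + shape) components.

No multiple-testing correction is applied, by design fidelity to the
original procedure.

# Classifiers

All three classifiers consume unit-variance-scaled features (division
by the training standard deviation; scaling parameters are refit per
fold and reused on the held-out subject).

**Self-organizing map.** Rectangular 6x6 lattice (configurable; the
original lattice size is unreported), Gaussian neighborhood
`h = exp(-||r_i - r_c||^2 / (2 sigma^2))`, two-stage schedule: an
ordering stage (100 epochs, learning rate 0.9 decaying linearly,
neighborhood radius from half the lattice down to 0.5) then a tuning
stage (1000 epochs, rate 0.5 decaying linearly, radius fixed at 0.5).
The stated tuning-phase values are the defaults; the ordering-stage
length and radius are this package's choices since only "fewer epochs,
higher rate, wider neighborhood" is specified. Rates decrease strictly
within each stage. Classification is by best-matching-unit label
(majority vote of training samples per node, ties to the earliest
class; unlabelled nodes defer to the nearest labelled node in lattice
distance) — the original work does not state a decision rule, so this
standard one is used and documented.

**Support vector machine.** One-against-rest soft-margin RBF machines.
The dual problem (maximize `sum(alpha) - 1/2 alpha' Q alpha` under
`0 <= alpha <= C`, `sum(alpha y) = 0`) is solved by sequential minimal
optimization with maximal-violating-pair selection, implemented in
C++. The kernel is the standard `exp(-gamma ||x - y||^2)` (the printed
kernel expression carries an obvious typesetting slip in its
exponent). Stopping: KKT gap below `tol` (default `1e-6`), scaled by
`sqrt(C)` for very large C where the gap's natural magnitude grows;
the suite checks the duals against an independent exhaustive
pairwise-ascent oracle to `1e-6` and the predictions against a
reference implementation. Prediction takes the class of maximal
decision value.

**PSO-SVM.** Particle swarm over `(log2 C, log2 gamma)` in
`[-5, 15] x [-15, 3]` (standard RBF grid conventions; the original
reports no bounds) with the stated settings: 30 particles, 200
iterations, `c1 = c2 = 2`, inertia `w = 0.8`, and patience 200 (inert
at the default iteration cap but configurable). Velocities are clamped
to 20% of each range; positions to the bounds. Particle fitness is the
stratified k-fold (default 5) cross-validated accuracy of an SVM at
the particle's parameters **on the training fold only** — a
leakage-free reading of the published "correct/total testing cases"
fitness, which taken literally would let the held-out subject steer
the hyperparameter search. The swarm is seeded to contain the
conventional default `(C = 1, gamma = 1/d)`, so the selected
parameters are never worse than the default under the internal
fitness. The final model is refit on the whole training fold at the
best position.

# Evaluation protocol

`loocv()` leaves one subject out at a time and refits *everything* —
scaling, screening, PCA, probability maps, classifier — on the
remainder; the held-out subject is transformed with the fold's fitted
parameters and predicted once. The published protocol descriptions
conflict (leave-one-out in one place, a fixed 22-case training split
elsewhere, with an inconsistent parenthetical count); leave-one-out is
implemented as the primary protocol.

Metrics follow `ACC = (TP + TN)/(P + N)`,
`TPR = TP/(TP + FN)`, `TNR = TN/(FP + TN)` on the two named classes'
rows of the confusion matrix. The package additionally reports the
**per-class accuracy** (diagonal over class total) because that is the
quantity the published per-task accuracy rows equal; several printed
confusion-matrix rows do not sum to their group sizes, so
`class_accuracy()` accepts an explicit class total for fixture
arithmetic. Percentages print at two decimals, rounded half up.

# The phantom generator

`generate_phantom()` builds a T1-like ellipsoidal brain on a
64 x 72 x 40 grid of 2.5 mm voxels (160 x 180 x 100 mm field of view):
a WM core, a GM shell, a thin peripheral CSF sheet, and a central
butterfly-shaped ventricular cavity — two mirrored teardrop lobes
(wide posterior bodies, narrower longer frontal horns) joined by a
thin midline bridge, so datum-slice descriptors, the left/right and
frontal/posterior sub-areas and landmark distances are all nontrivial.
Class intensities default to CSF 40, GM 110, WM 170 with Gaussian
noise of s.d. 8 inside the brain — intensity separations of several
noise s.d., comparable to good-quality T1 tissue contrast. The voxel
size makes the cavity many voxels thick, as real ventricles are at
MRI resolution, so that radius-1 morphology is a small perturbation.

Disease is modelled by `ventricle_scale` (cavity volume multiplier)
with `horn_asymmetry` lengthening the frontal horns; the same
parameter drives cortical atrophy (thinner GM shell, smaller WM core,
thicker peripheral CSF), so GM and WM shrink while CSF, ventricular
volume, datum-slice area and landmark distances grow from NC through
MCI to AD — the direction reported for real cohorts. Cohort presets
are NC 1.0, MCI 1.25, AD 1.5 with per-subject lognormal jitter of
s.d. 0.05: strong, clearly separated effects chosen once to emulate a
well-separated clinical cohort (published group differences on these
markers are all significant at p < 0.05 despite n ~ 17). Default
cohort sizes are 17/18/17.

Determinism: all generation flows through `with_seed()`, which derives
per-subject seeds from one master seed and restores the caller's RNG
state; equal seeds give bit-identical cohorts.

**What the phantoms do not show.** No MRI physics (bias fields,
partial-volume averaging, Rician noise), no registration error, no
anatomical variability beyond the parametrized geometry, no skull. A
pipeline that classifies phantom cohorts perfectly demonstrates the
machinery end to end — correct plumbing, leakage-free validation,
sane features — not clinical accuracy; the published clinical figures
are reproduced only at the level of their metric arithmetic, from the
printed confusion matrices.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full study at 52
subjects with the PSO budget reduced to 10 particles and 50 iterations
— past that point the search is saturated on well-separated cohorts —
and the SMO tolerance relaxed to `1e-3` inside the PSO fitness (the
final model is always refit at `1e-6`). Oracle comparisons use >= 200
random instances per operation at tolerance `1e-6`; Mann-Whitney
calibration uses 10,000 null replicates at n = 17 vs 18. Ties are
broken deterministically everywhere: lowest index for BMU and datum
slices, earliest class level for label votes, first class for equal
SVM decision values.

# Known limitations

* The intensity-only mixture has no spatial regularization, so heavy
  noise (s.d. approaching the class separation) degrades segmentation
  faster than an atlas-based method would.
* Perimeter (hence circularity) is resolution dependent at very coarse
  grids, as for any traced digital contour.
* The SOM decision rule and several descriptor definitions are
  package-fixed conventions where the source material is silent; they
  are documented above and in the function reference.
* With `max_iter = 200` and `patience = 200`, the PSO patience rule
  never fires at defaults; both remain configurable.
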