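---
title: "Building and validating virtual TAVI cohorts with vcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating virtual TAVI cohorts with vcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcohort)
```

## The problem

In-silico trials test cardiovascular devices on virtual patients instead of
(or before) real ones. For transcatheter aortic valve implantation (TAVI)
this requires a credible population of aortic-root anatomies — wall geometry
plus the calcific plaques that anchor the device — spanning the anatomical
variability of the target population. `vcohort` implements the full chain:

1. **Correspondence.** Per-patient 3D point clouds (wall and calcification,
   read from STL/PLY) are registered to a common template: rigid iterative
   closest point (ICP), then similarity ICP (adding an isotropic scale), then
   a smoothed closest-point warp of the template onto each subject. The warp
   output has the template's point count and ordering, which is what creates
   dense correspondence. The whole procedure is iterated against the evolving
   mean shape so the arbitrary initial reference does not bias the atlas.
2. **Statistical shape model (SSM).** PCA of the corresponded coordinate rows
   (SVD of the centred matrix, covariance divisor N−1) gives a mean shape,
   orthonormal deformation modes φ_j and per-mode variances λ_j. A shape is
   `mean + Σ_j w_j σ_j φ_j` with weights in σ units.
3. **Virtual cohort.** New anatomies are sampled by drawing each of the
   leading modes (those retaining 90% of the variance) uniformly from the
   discrete grid {−2σ, −1.5σ, …, +2σ}, deforming the mean, annotating each
   shape with an occurrence probability, and rejecting implausible (folded or
   self-intersecting) geometry.
4. **Validation and shape–function links.** Annulus diameter and
   calcification volume of the virtual cohort are compared with the training
   population (Mann–Whitney U); mode scores feed Pearson correlations, an
   SVM regression of the transvalvular peak pressure gradient, and
   device-size classifiers.

## Model assumptions

* Shape variability is well approximated by a linear point-distribution
  model: each anatomy is the mean plus a linear combination of modes. This is
  the standard SSM assumption; strongly non-linear variation (e.g. bicuspid
  valves) is out of scope.
* Calcific plaques are assumed present on all three valve leaflets, so a
  single plaque template can be warped onto every subject. Plaque patterns
  that violate this (single-leaflet calcification) will correspond poorly.
* The similarity scale estimated during alignment is *kept* in the
  corresponded rows (it is undone after warping, about the template
  centroid). Mode 1 of the wall model therefore captures overall size —
  the dominant, clinically meaningful factor. Normalizing size away instead
  would redistribute it into correlated residual modes.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| ICP tolerance | 0.01 mm | stop when the mean displacement induced by the three most recent transform estimates is below this |
| ICP iteration cap | 120 | hard stop; result flagged not-converged |
| plaque ICP tolerance | 0.2 mm | relaxed tolerance for the plaque-only alignment, avoiding excessive rotation/translation of sparse plaques |
| warp bandwidth | 5% of template bbox diagonal (wall); 1.5 mm (plaques) | Gaussian smoothing of the displacement field |
| warp iterations | 10 (wall), 15 (plaques) | closest-point/smooth rounds |
| mean-shape tolerance | 0.05 mm | outer re-alignment loop stop, max 10 rounds |
| retained variance | 90% | modes varied when sampling virtual patients |
| sampling boundary / step | ±2σ / 0.5σ | discrete uniform grid per mode |
| selected modes (ML) | 6 | by \|Pearson r\| (regression) or ANOVA F (classification) |
| CV folds / split | 10 / 70:30 | regression tuning / classifier evaluation |

The plaque-specific warp bandwidth deserves a note: plaques are ~4 mm
structures, and a wall-scale kernel (≈2–4 mm at typical extents) averages
across a whole plaque. That under-fits the warp and systematically shrinks
corresponded plaque volumes — visible as a downward bias in the virtual
cohort's calcification volumes. A 1.5 mm bandwidth with 15 iterations removes
the bias while keeping the field smooth at the plaque scale.

## Occurrence probability

For a mode deviation of b·σ the package reports the standardized upper-tail
probability `1 − Φ(b)`: 30.85% at 0.5σ, 15.87% at 1σ, 6.68% at 1.5σ, 2.28%
at 2σ, 0.62% at 2.5σ, 0.13% at 3σ. With the ±2σ sampling boundary, every
emitted deviation has occurrence probability at least 2.28%, i.e. only the
rarest ~2% of per-mode variation is excluded from the virtual cohort. A
chi-square variant (`shape_probability_chisq()`, upper tail of the squared
Mahalanobis distance at 3 degrees of freedom) is exposed for users who prefer
the multivariate reading; the two do not agree numerically and the
standardized tail is the reporting convention here.

```{r}
shape_probability(c(0.5, 1, 1.5, 2, 2.5, 3))
```

## Plausibility screening

Visual inspection of synthetic anatomies does not scale, so rejection is
automated. With a triangulated surface two tests run: no pair of non-adjacent
triangles may intersect (grid-accelerated triangle–triangle test), and at
least 99% of face normals must agree in direction with the mean shape's
normals. For faceless clouds (the usual case after random resampling) the
fallback is neighbourhood preservation on the k-nearest-neighbour graph: the
deformation must be locally injective — a point's nearest deformed neighbour
must already be among its 20 nearest neighbours on the mean shape for ≥99%
of points. A surface folded through the opposite wall fails either
formulation. The 99% thresholds tolerate numerical noise at mesh seams;
rejected shapes are redrawn (up to 50 attempts) with logged seeds.

## The synthetic-data generator

No patient data ship with the package, so `synth_cohort()` generates a
reference population with known ground truth: 68 patients by default, wall
clouds as tubes of varying radius along a quadratic centerline with three
sinus bulges, calcifications as three ellipsoidal plaque blobs at the
leaflet positions, each anatomy emitted under a random rigid motion (axis
uniform, angle ≤20°, shift ≤20 mm — emulating scanner-frame variability) so
registration is genuinely exercised.

Six latent z-scores drive the geometry: global **scale** (SD 2.5% of size),
centerline **curvature** (bow 3±3 mm), **annulus** radius (local modulation,
SD 1.5 mm at the base), **sinus width** (bump amplitude 0.35±0.10), plaque
**volume** (±25%) and inter-plaque **gap** (2±0.8 mm axial stagger). These
were chosen once so that the fitted wall atlas shows the qualitative mode
semantics reported for real TAVI populations — mode 1 ≈ size, mode 2 ≈
curvature, then annulus and sinus — with a realistic annulus spread
(≈23±3 mm) straddling the 23/26 mm device-size boundary. The parametric
sampling pattern (the (v, θ) draws and surface noise, 0.15 mm) is shared
across patients, so identical latents produce identical clouds and
between-patient variation is pure shape.

The clinical table reproduces the pre-TAVI characteristics of a
severe-stenosis population (age 80.5±6.0 y, peak gradient
79.11±14.59 mmHg, and so on);
the peak gradient is linked linearly to the scale, annulus and
plaque-volume latents with Gaussian noise calibrated to a generative
R² ≈ 0.6, and the device label follows a 23 mm annulus-diameter threshold
with 5% label noise. Internally consistent quantities (BMI, BSA, jet
velocity via the simplified Bernoulli relation, cardiac output) are derived,
not drawn.

**What the generator does not emulate:** real segmentation noise and
operator variability, native leaflets, non-tricuspid morphologies,
single-leaflet or free-floating calcification patterns, and the
high-dimensional residual variability of real anatomy (the synthetic atlas
is low-rank by construction, so far fewer modes reach 90% variance than the
~25–32 needed on real cohorts). Passing tests on synthetic cohorts therefore
demonstrate the correctness of the machinery — registration, PCA,
sampling, measurement, statistics — not clinical validity on any particular
patient population.

## Numerical choices

* **ICP stop rule.** "Average difference between the three most recent
  transform estimates" is operationalized as the mean point displacement the
  consecutive estimates induce on the moving cloud, averaged over the last
  three iterations — a length in mm, directly comparable to the 0.01 mm
  tolerance.
* **ICP initialization.** ICP is a local optimizer; it starts from the best
  (lowest mean closest-point distance) of five coarse poses: centroid
  alignment plus the four proper-rotation matchings of the clouds' principal
  axes.
* **Reference selection.** When no reference subject is named, the subject
  whose annulus diameter (walls) or centroid size (calcifications) is closest
  to the cohort median is used, minimizing the initial template bias.
* **PCA via SVD** of the centred data matrix, never an explicit covariance,
  for numerical stability; modes with λ < 1e−12·λ₁ are discarded; each
  mode's sign is pinned (largest-magnitude entry positive) so results are
  deterministic.
* **Generalization norm.** The leave-one-out reconstruction error uses the
  per-point RMS Euclidean distance (mm), which is independent of the
  template resolution. Folds reuse the cohort's existing correspondence; the
  registration is not recomputed per fold (the left-out subject's rows were
  produced with a template that saw it, a small optimism common to SSM
  quality reporting).
* **Annulus diameter.** The proximal end slab (smaller median radius) is
  found along the principal axis, the rim plane is re-estimated locally
  (minimum-variance direction of the slab) to remove curvature-induced tilt,
  and the area-derived diameter 2√(A/π) of the projected band's convex hull
  is returned — the TAVI-sizing convention. At the reduced 2,000-point
  working resolution the pipeline measures with a 2 mm band (the 1 mm
  default suits denser clouds).
* **Calcification volume** sums per-plaque convex-hull volumes over
  density clusters (single linkage at 2 mm, clusters under 20 points
  discarded), so disjoint plaques do not inflate the estimate.
* **Mann–Whitney tests** use the exact distribution for small untied
  samples and the tie-corrected normal approximation otherwise.
* **Bayesian tuning.** The SVR hyperparameters (log₁₀C ∈ [−2, 3],
  log₁₀γ ∈ [−3, 1], degree ∈ {2, 3, 4}) are tuned by a Gaussian-process
  surrogate with expected improvement: 8 space-filling evaluations, then 12
  EI-guided ones, minimizing 10-fold CV RMSE, all seeded.
* **R² reporting.** Out-of-fold R² (predictive) and refit-on-all R²
  (in-sample) are reported separately; out-of-fold is the headline number.
  Note that even a correctly specified model shows out-of-fold R² below the
  generative value at n = 68 (CV shrinkage).
* **MLP architecture.** One hidden layer with twice as many units as
  features, weight decay 0.01, 500 iterations; stated here because the
  classification results are only auditable with the architecture pinned.

## Design choices where the design was open

* The non-rigid correspondence algorithm is a deliberately simple smoothed
  closest-point warp (a stand-in for heavier tools like Amberg or coherent
  point drift): each template point moves 70% of the way toward its smoothed
  closest-point displacement per iteration. It is transparent, fast, and
  sufficient for tube-like anatomy; sliding or strongly re-parameterizing
  correspondence is beyond it.
* Grid-resolution convergence uses the first mode's explained-variance
  *fraction* (dimensionless) as the tracked quantity with the 5% relative
  change rule; eigenvalues would confound resolution with physical scale.
* Virtual-shape weights are uniform over the discrete σ grid, independent
  across modes — the least-informative choice consistent with bounded
  stepped sampling; wall and calcification weights are drawn independently
  with a shared seed stream so patient pairs are reproducible.
* A shape's occurrence probability is annotated at its most extreme mode
  deviation (the binding boundary for that shape).
* The ML stages consume wall and calcification mode scores side by side:
  both anatomies carry functionally relevant information (e.g. plaque burden
  drives the transvalvular gradient, annulus size drives device choice).

## Problem sizes

Default working resolutions are 2,000 wall / 1,500 calcification points and
68 synthetic patients; the full pipeline (alignment, atlas, 100 virtual
patients, validation, regression, classification) then runs in about a
minute on a laptop core. Production atlases at 30,000/50,000 points are
configured the same way (`synth_config(wall_points = 30000, ...)` or real
STL inputs) and scale roughly linearly in points × subjects × mean-shape
rounds. Test-suite cohorts are smaller still (hundreds of points, 4–40
subjects); the vignette's numbers and the package's acceptance summaries are
computed at the defaults.

## Known limitations

* Correspondence quality for calcification is inherently limited: plaques do
  not truly correspond across patients; the three-leaflet assumption is a
  modelling convenience and single-leaflet patterns will be smeared.
* The occurrence-probability table is a per-mode (marginal) quantity, not
  the joint probability of a whole weight vector.
* Leave-one-out generalization without per-fold re-registration is slightly
  optimistic (above).
* The discrete uniform sampling grid inflates per-mode weight variance
  relative to the training distribution (uniform on ±2σ in 0.5σ steps has
  variance 1.67σ²); medians are preserved, which is what the Mann–Whitney
  validation tests.
* The SVM regression's out-of-fold R² depends on the mode-selection step
  seeing all subjects (selection is not nested inside the folds), matching
  common practice but mildly optimistic.
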