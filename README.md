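# vcohort

Virtual patient cohorts for in-silico TAVI trials: statistical shape
modeling of the aortic root and its calcific plaques, bounded shape-mode
sampling of synthetic anatomies, morphometric validation, and shape–function
machine learning.

`vcohort` is for researchers building in-silico trials of transcatheter
aortic valve implantation (TAVI) devices: it turns a set of per-patient 3D
surfaces (aortic wall + calcification, STL or PLY) plus a clinical table
into (i) a PCA shape atlas, (ii) a validated cohort of synthetic anatomies,
and (iii) statistical links between shape and valve function or device
sizing.

## The model

Each subject's surfaces are brought into dense correspondence with a
template — rigid, then similarity (rigid + isotropic scale) iterative
closest point registration (tolerance 0.01 mm, ≤120 iterations), followed by
a Gaussian-smoothed closest-point warp of the template onto the subject; the
procedure is iterated against the evolving mean shape. Stacking the
corresponded coordinate rows x_i and applying PCA gives the
point-distribution model

    x ≈ x̄ + Σ_j w_j σ_j φ_j ,

with orthonormal modes φ_j, mode standard deviations σ_j and weights w_j in
σ units. Atlas quality is summarized by the compactness (cumulative variance)
and the leave-one-out generalization

    GE(M) = (1/N) Σ_i ‖ x_i − x̂_i(M) ‖ ,

where x̂_i(M) is the left-out subject rebuilt from the first M modes and the
norm is the per-point RMS distance in mm.

Virtual patients are drawn by sampling the modes that retain 90% of the
variance uniformly on the grid {−2σ, −1.5σ, …, +2σ}; each anatomy carries
the occurrence probability 1 − Φ(b) of its most extreme deviation b (30.85%
at 0.5σ down to 2.28% at the 2σ boundary) and passes an automated
fold/self-intersection screen. The virtual cohort is validated against the
training population with Mann–Whitney U tests on annulus diameter and
calcification volume. Mode scores then feed Pearson correlations, a
polynomial-kernel SVM regression of the transvalvular peak pressure
gradient (Bayesian-tuned, 10-fold cross-validated), and four classifier
families (MLP, logistic, KNN, SVM) predicting the implanted device size
(23 vs 26 mm) from F-score-selected modes.

No patient data ship with the package; a parametric generator
(`synth_cohort()`) emulates a 68-patient TAVI population with known latent
anatomy factors and a linked clinical table, so the entire pipeline is
reproducible and testable end to end.

## Worked example

```r
library(vcohort)

res <- run_pipeline(run_config(output_dir = "run1", seed = 1))

res$fit$wall
#> <shape_model> wall: 67 modes from 68 subjects (2000 points)
#>   variance fractions: 52.2% 23.8% 16.8% 6.5% 0.3% 0.2% ...

res$validate$report
#> <validation_report> real n=68 vs synthetic n=100
#>   annulus_mm: U = 3075.0, p = 0.294
#>   calc_volume_mm3: U = 3840.0, p = 0.156

res$regress
#> <regression_result> modes {70, 1, 3, 129, 91, 11}; C = 13.171, degree = 2, gamma = 0.004
#>   CV RMSE = 10.56, out-of-fold R^2 = 0.498 (refit-on-all R^2 = 0.552)

res$classify
#> <classification_result> test n = 20  classes: 23 vs 26
#>   mlp      accuracy 0.800  AUROC 1.000
#>   logistic accuracy 0.750  AUROC 0.848
#>   knn      accuracy 0.700  AUROC 0.798
#>   svm      accuracy 0.850  AUROC 0.909
```

Reading the output: the wall atlas is dominated by a size mode (52% of
variance), all 100 sampled anatomies passed the plausibility screen, and the
virtual cohort is morphometrically indistinguishable from its training
population (both Mann–Whitney p-values ≫ 0.05 — non-significance is the
desired outcome here). The SVM regression explains about half of the
out-of-fold variance in the peak gradient (CV RMSE ≈ 10.6 mmHg), and the
MLP separates the two device-size groups essentially perfectly on the
held-out 30%.

Individual stages are exposed as plain functions (`read_surface()`,
`resample_surface()`, `align_cohort()`, `align_calcifications()`,
`ssm_fit()`, `ssm_deform()`, `generate_cohort()`, `compare_cohorts()`,
`svm_regress()`, `classify_device_size()`, …) and through a thin CLI at
`inst/cli/vcohort` (`vcohort run --config cfg.yaml`, `vcohort synth`,
`vcohort resample`, `vcohort probability`).

See `vignettes/virtual-cohorts.Rmd` for the methods account: model
assumptions, parameter defaults and their rationale, what the synthetic
generator does and does not emulate, and known limitations.

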