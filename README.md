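# chronact

Chronic active lesion analysis for longitudinal multiple-sclerosis MRI.

In MS, a subset of white-matter lesions stays inflamed for years after
formation ("chronic active" or smouldering lesions). Two MRI markers
identify them non-invasively:

* **SELs** (slowly expanding lesions): lesions whose volume creeps up
  across serial scans. Given a displacement field `u(x)` mapping the
  baseline scan to a follow-up, the local volume change is the Jacobian
  determinant `J(x) = det(I + ∇u(x))`; `J > 1` means expansion. A lesion's
  expansion summary is its annualized mean log-Jacobian,
  `m = mean(log J over lesion voxels) / Δt`, z-scored within patient and
  graded into *possible* and *definite* SELs.
* **PRLs** (paramagnetic rim lesions): lesions ringed by iron-laden
  microglia, visible as a hypointense rim on susceptibility-weighted
  imaging (SWI). The package replaces visual rating with a deterministic
  rule: a shell voxel is rim-dark when its intensity falls below
  `min(core mean, ring mean) − k·SD(ring)`; a lesion is a PRL when the
  dark fraction of its boundary shell exceeds `c_min`, the rim persists on
  ≥ 2 consecutive axial slices, and the dark structure is not tubular
  (vein-like by second-moment elongation).

Downstream, the package reproduces the cohort statistics used to study
these markers: the lesion-level SEL × PRL cross-tab (chi-square with Yates
correction), patient stratification (SEL+PRL+ / SEL+PRL− / SEL−),
Spearman and partial rank correlations, Poisson / log-linear count and
volume models, a logistic model of confirmed disability progression
(CDP), and a linear mixed model of per-visit EDSS with per-stratum time
slopes and a patient random intercept:

```
EDSS_ij = β0 + stratum_i + (β_stratum · t_ij) + γ·covariates_i + b_i + ε_ij
```

Because no clinical MRI can be redistributed, the package ships a fully
ground-truthed **synthetic cohort generator**: multi-channel NIfTI volumes
with implanted ellipsoidal lesions, analytic radial displacement fields
(closed-form Jacobians), SWI rims and vein confounders, and EDSS
trajectories whose slopes depend on the SEL/PRL stratum. Every pipeline
stage is tested against this known truth.

## Worked example

```r
library(chronact)

cfg <- sim_config(seed = 42, n_patients = 8)   # small demo cohort
res <- run_all(cfg)                            # simulate -> detect -> analyze

res$analysis$crosstab$table
#>         PRL no PRL
#> SEL       8     65
#> non-SEL   2     93

round(res$analysis$crosstab$row_prop, 2)
#>     SEL non-SEL
#>    0.11    0.02

res$analysis$strata_counts
#> SEL_PRL_BOTH     SEL_ONLY      SEL_NEG
#>            4            4            0

fit <- res$analysis$edss_mixed
fit$coef[grep(":time", fit$coef$term), ]
#>                       term   beta    ci_lo ci_hi      p
#> 7 stratumSEL_PRL_BOTH:time 0.1560  0.00552 0.306 0.0422
#> 8     stratumSEL_ONLY:time 0.0214 -0.08018 0.123 0.6796
```

Reading the output: 11% of detected SELs carry a rim versus 2% of
non-SELs (the co-occurrence enrichment); 4 of 8 patients have both
markers; and the SEL+PRL+ group's fitted EDSS slope is 0.156 points/year
(95% CI 0.006–0.306) against a generating slope of 0.15 — the marker
combination, not either marker alone, carries the disability signal.
Against ground truth this run recovers SEL labels perfectly and PRLs at
sensitivity 0.77 / specificity 1.00 (small-cohort draw; on the default
61-patient world the acceptance suite requires ≥ 0.90 / ≥ 0.90 for both).

The same pipeline is scriptable from the shell:

```sh
inst/cli/chronact simulate   --seed 1 --n-patients 4 --out cohort/
inst/cli/chronact detect-sels --labels cohort/patient_001/labels.nii.gz \
    --field cohort/patient_001/field.nii.gz --years 3.2 --out lesions.csv
inst/cli/chronact detect-prls --swi cohort/patient_001/swi.nii.gz \
    --labels cohort/patient_001/labels.nii.gz --out rims.csv
inst/cli/chronact run-all    --seed 1 --out report/
```

## Layout

* `R/volumes.R`, `R/nifti.R` — volume/label/field data model, NIfTI-1 I/O
* `R/morphology.R`, `R/resample.R`, `R/jacobian.R` — voxel primitives
  (Rcpp kernels in `src/voxel_ops.cpp`)
* `R/sel.R`, `R/prl.R` — SEL and PRL pipelines
* `R/stats.R` — cohort statistics and models
* `R/simulate.R` — synthetic cohort generator
* `R/cli.R`, `inst/cli/chronact` — workbench and command line
* `vignettes/chronact-methods.Rmd` — models, assumptions, parameter
  choices, and what the synthetic world does and does not establish
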