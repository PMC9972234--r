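---
title: "chronact: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chronact: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the models it
fits, the parameters that matter, what the synthetic world emulates, and
where the design was genuinely open. It states no empirical number that
the test suite does not itself compute.

## 1. The problem

Chronic active (smouldering) MS lesions damage tissue for years behind an
apparently stable T2 appearance. Two imaging surrogates exist: slow
radial expansion on serial volumetric MRI (SELs) and an iron rim on
susceptibility-weighted imaging (PRLs). `chronact` implements both
detectors plus the cohort-level statistics that relate them to each other
and to disability, and a ground-truthed simulator that makes the whole
chain testable without patient data.

## 2. SEL detection

**Model.** A displacement field `u(x)` (mm, stored on the baseline
lattice) maps baseline anatomy to the final follow-up. The local volume
ratio is `J(x) = det(I + ∇u(x))`. `∇u` is taken in world units with
per-axis voxel spacing — central differences at interior voxels,
one-sided at grid boundaries; for affine fields this is exact, which the
tests exploit (`J = det(A)` to 1e-10). An optional Gaussian
pre-smoothing of the field (`sigma`, mm; default 0) is exposed because
the amount of smoothing applied before differentiating is genuinely
unknowable from outside a given registration pipeline.

**Summaries.** Only lesions strictly over 10 mm³ are classified. Per
lesion we report `mean J` and the annualized mean log-Jacobian
`m = mean(log J)/Δt`. The mean of `log J` (not the log of the mean) is
used so that yearly field compositions add: if the same field acts two
years running, `m` is unchanged.

**Grading.** Within a patient, `z = (m − mean)/sd` (sample sd) over that
patient's eligible lesions. Classification (`sel_config()`):

* definite SEL: `m ≥ τ_abs` and `z ≥ z_def` (default 1.0);
* possible SEL: `m ≥ τ_abs` and `z_def > z ≥ z_pos`;
* otherwise non-SEL. The combined "SEL" flag is possible-or-definite.

Defaults: `τ_abs = 0.002`/yr, `z_pos = -Inf`, `z_def = 1.0`. The choice
of `z_pos = -Inf` — i.e. *detection* is purely absolute and the z-score
only *grades* candidates — is deliberate. A finite detection gate on the
within-patient z-score penalises exactly the patients the marker matters
for: when ~40% of a patient's lesions expand, the patient's own mean
expansion is substantially positive, and slow-but-real expanders fall
below any positive z cut. Simulating the default world shows a z ≥ 0.5
detection gate caps combined-SEL sensitivity near 0.87 while adding
nothing to specificity (non-expanding lesions are already excluded by
`τ_abs`). The z-score's legitimate job — separating *definite* from
*possible* in a follow-up-time-robust way — is retained through `z_def`.
Patients with a single eligible lesion (z undefined) or identical
summaries (sd = 0) fall back to the absolute threshold and are graded at
most possible; the `z_fallback` column records this.

Concentricity or constant-growth checks used by some SEL pipelines are
not implemented: the detection contract here is expansion by Jacobian
alone.

## 3. PRL detection

The visual criteria are operationalised as follows (`prl_config()`):

1. *Rim hypointensity relative to core and surrounding white matter.*
   Shell/core/ring masks come from 6-connected erosion (1 voxel) and
   dilation (2 voxels) of the lesion in SWI voxel space, with other
   lesions excluded from the ring. A shell voxel is rim-dark when its
   intensity is below `min(core mean, ring mean) − k·SD(ring)`, `k = 1.5`.
   All cuts are in ring-SD units, so scoring is invariant under affine
   intensity rescaling. **Degenerate core:** on 3 mm slices a lesion
   spanning two slices loses its entire core to erosion; the reference
   then falls back to the ring alone. Without this rule the cut becomes
   self-referential (the shell compared to its own mean) and genuine rims
   are invisible.
2. *Correspondence to the FLAIR lesion edge* is enforced by construction:
   lesion identifiers are carried from FLAIR space into SWI space by
   nearest-neighbour resampling in world coordinates, so every scored
   shell belongs to a FLAIR lesion. A lesion that vanishes in resampling
   is scored "absent", never a PRL.
3. *Visible on ≥ 2 consecutive slices.* Per axial slice, the slice is
   rim-bearing when its shell dark-fraction reaches `c_slice = 0.2`; the
   longest consecutive run must reach 2. This criterion is exact: no
   single-slice rim is ever a PRL.

A lesion is a PRL when overall shell coverage reaches `c_min = 0.25`
("partial" rims are admitted — the published criteria are explicit that a
partial rim counts; 0.25 is our declared operationalisation, not an
inferred rater threshold), the slice rule holds, and the dark structure
is not vein-like. Vein-likeness is decided per connected dark component
(shell ∪ ring) by second moments in world mm: elongation
`sqrt(λ1/λ2) ≥ 3` with cross-section thickness `2·sqrt(λ2) ≤ 2 mm`
(the spec-sheet phrase "voxels" is ill-defined on a 0.65×0.65×3 mm
lattice, so thickness is metric). A lesion is discounted when most
(≥ 50%) of its dark shell sits in such components.

## 4. Cohort statistics

* **Cross-tab**: SEL × PRL counts with per-row PRL proportions;
  chi-square on 1 df *with Yates continuity correction* — only the
  corrected statistic reproduces the published p = 0.027 from the
  published table's counts (the uncorrected value is ≈ 0.020). Empty
  margins skip the test but keep the table.
* **Strata**: SEL+PRL+ / SEL+PRL− / SEL− (the SEL-negative subsets with
  and without PRLs are pooled; they are too small to split).
* **CDP**: EDSS worsening ≥ 1.5 from baseline 0 or ≥ 1.0 from baseline
  > 0, reached at the final scan and sustained at a confirmation visit
  ≥ 0.5 years later. Fewer than three visits → undetermined (`NA`),
  which is deliberately distinct from `FALSE`.
* **Correlations**: Spearman; the partial variant regresses the ranks of
  both variables on the ranks of the control and correlates residuals
  (no canonical method is published; this is the declared choice).
  Approximate CIs use the Fisher transform with the 1.06/(n−3) variance
  correction for rank correlations.
* **Mixed model**: per-visit EDSS, REML, random intercept per patient,
  fixed effects metric + metric×time + covariates (age, sex, relapse
  count, log baseline lesion volume, treatment status). For the stratum
  metric the interaction is parameterised as *per-stratum slopes*
  (`~ stratum + stratum:time`), so each coefficient is that group's own
  EDSS slope in points/year — the only parameterisation in which a
  "slope of 0.15/year" is a single coefficient. Wald 95% CIs and Wald-z
  p-values are reported. The published analysis is ambiguous between a
  change-score outcome and per-visit EDSS; per-visit is the only form
  consistent with per-year slopes, and the change-score alternative is
  recoverable by differencing.
* **Counts and volumes**: Poisson (log link) for counts — no exposure
  offset, matching the ambiguity in the source analysis — and OLS on
  log-volumes with a Shapiro–Wilk residual check; zero volumes are
  excluded from the log model and counted.
* **Reporting**: percentages are rounded half-up to whole percent
  (91.8 → 92, 50.8 → 51), ratios to two decimals, matching the published
  tables' conventions. No multiple-testing adjustment anywhere.

## 5. The synthetic world

Defaults (`sim_config()`) encode the emulated cohort: 61 patients;
negative-binomial lesion counts (size 2, mean 23 → median ≈ 20, clamped
to [1, 80]); 41% of lesions truly expanding with annual radial growth
uniform on 1.02–1.05; rim probability 0.07 given expansion and 0.04
otherwise (marginal ≈ 0.05, and the published 7% vs 4% enrichment by
construction); follow-up uniform on 0.7–8.3 years with an intermediate
scan at 30–60% of follow-up; baseline EDSS from a gamma draw rounded to
the half-point grid and clamped to [0, 4.5] (median ≈ 1.5); stratum EDSS
slopes 0.15 / −0.02 / −0.11 points/year with visit noise SD 0.5 (typical
EDSS inter-rater error) before grid rounding; demographics and brain
volume covariates (NBV/CGM/DGM/BPF) as Gaussian scalars around the
published cohort means. Images: 96³ voxels at 1 mm (analysis lattice)
and a 0.65×0.65×3 mm SWI lattice; two-tissue background; intensity noise
SD 0.05 against O(1) tissue contrast; rim depth 3 noise-SDs at 90% shell
coverage; 4 vein confounders per patient (tubes 20–40 mm long, 0.8 mm
wide, 3 SD dark).

**Displacement fields are analytic.** Each expanding lesion gets a pure
radial scaling `u(x) = (s − 1)(x − c)` out to core radius
`r0 = rmax + 1.5 mm` (covering the lesion and the finite-difference
stencil), tapered to identity at `3·r0` by a C¹ smoothstep; `s = g^T`
for annual growth `g` and follow-up `T`. Inside the core `J = s³`
*exactly*, so per-lesion mean log J equals `3·T·log g` to machine
precision and the annualized summary equals `3·log g` independent of
follow-up time — the property the acceptance tests assert at 1e-3.
Lesion centres are placed by rejection sampling so no lesion intrudes on
another's taper support; when a crowded draw cannot be placed it is
dropped (the ground-truth table contains placed lesions only). The taper
slope bounds `s < 1.8` for positivity of `J`; the default world peaks at
`1.05^8.3 ≈ 1.5`.

**Rim-bearing lesions are drawn from the upper size range** (z semi-axis
≥ 3.3 mm, in-plane ≥ 2.4 mm): a 3 mm-slice SWI cannot depict a rim on a
lesion thinner than two slices, a physical constraint the visual raters
faced too. Veins are rasterized along their centre-line before
thickening, so an oblique sub-voxel-width vein remains a 26-connected
tube rather than per-slice dots.

**What a green test does and does not establish.** The generator shares
the package's own geometry code for shells and resampling, so rim
implantation and rim detection agree on what "the shell" is; a green PRL
test therefore validates the decision rule and its invariances, not an
independent physics model of susceptibility contrast. Similarly the
displacement fields are noise-free and compactly supported: SEL recovery
on this world demonstrates correctness of the Jacobian pipeline and
thresholds, not robustness to registration error, which real deformation
fields would carry. Clinical realism not modelled: MR physics (phase,
relaxometry), bias fields, lesion confluence, rim evolution over time,
and treatment effects.

## 6. Numerical choices and degenerate inputs

* Jacobian stencils: central/one-sided differences; grids must span ≥ 3
  voxels per axis; `J ≤ 0` inside a lesion is an error (non-diffeomorphic
  input), not a silent NaN.
* Nearest-neighbour resampling is "nearest source centre in world
  coordinates", including outside the grid (clamped), with an exact
  per-axis fast path for diagonal affines and a windowed search
  otherwise; ties (exactly equidistant centres) may resolve either way,
  and tests use tie-free geometry.
* Connected components are 26-connected, labelled in decreasing size
  order; shells use the 6-connected structuring element, one iteration
  per voxel of erosion/dilation; outside the grid is background.
* Empty masks, empty cohorts, all-constant SWI, single-lesion patients,
  lesions lost in resampling, empty contingency margins, all-zero counts
  and separated logistic fits are all defined (flagged) outcomes, not
  errors; genuinely impossible requests (negative spacing, J ≤ 0,
  missing lesion ids) fail fast with messages.
* Determinism: every stochastic draw derives from the config seed via a
  fixed per-patient mixing function; `run_all` with the same seed writes
  byte-identical CSVs, which the suite asserts.
* The noiseless mixed-model identifiability check disables EDSS grid
  rounding (`round_edss = FALSE`): quantisation to half-points is part
  of the default world but bounds any estimator's accuracy at the
  quantisation scale, which would mask the 1e-6 claim being tested.

## 7. Known limitations

* The NIfTI-1 implementation covers the common single-file dialect
  (datatypes uint8/int16/uint16/int32/float32/float64, sform/qform,
  gzip); NIfTI-2, ANALYZE and multi-file pairs are out of scope.
* PRL thresholds are an operationalisation of a visual standard; their
  absolute values are meaningful only relative to this package's shell
  definition and the synthetic contrast model.
* The vein filter is geometric; a vein running tangentially *within* a
  rim plane is indistinguishable from rim signal at this resolution.
* Mixed-model p-values are Wald-z, slightly anticonservative at small n
  compared to Satterthwaite degrees of freedom.
* The simulator fixes FLAIR-like images at the 1 mm analysis lattice;
  the acquisition-resolution 2-D FLAIR and its resampling are not
  modelled.
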