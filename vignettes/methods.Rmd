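---
title: "Classifying cognitive status from functional connectomes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cognitive status from functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific content of `pdcognet`: the models
each stage implements, the tunable parameters and why their defaults are
what they are, what the synthetic cohort generator does and does not
emulate, and the design decisions taken where the methodology left
genuine freedom.

## The problem

Mild cognitive impairment (MCI) in Parkinson's disease (PD) raises the
risk of later dementia, so a non-invasive marker separating PD patients
with MCI from those without is clinically interesting. The approach
implemented here classifies patients from *connection-wise* resting-state
functional connectivity: each subject is represented by the vector of
partial correlations between all pairs of atlas regions, a sparse subset
of discriminative edges is chosen by stability selection, and a linear
support vector machine (SVM) is cross-validated at the single-subject
level. Permutation null models and network-based statistics quantify
whether performance and group differences exceed chance.

## Signal conditioning

**Bandpass filter.** `bandpass_filter()` applies a zero-phase
(forward-backward) Butterworth bandpass of order 4, default 0.01–0.1 Hz,
to each node series. Only the band is scientifically prescribed; the
filter family and order are implementation choices, and the zero-phase
realization was chosen because phase lag would distort the correlation
structure that downstream stages rely on. Series are demeaned before
filtering to shorten edge transients. Order of operations (filter, then
extract eigenvariates) is likewise a choice, flagged here: both maps are
linear, so they commute up to the dominance of the leading component.

**Eigenvariates.** `first_eigenvariate()` returns the leading right
singular vector of the row-centered voxel-by-frame matrix — the single
time course that explains the most variance of a region's voxels. SVD
leaves a sign ambiguity; it is resolved deterministically by requiring
the sum of the voxel weights to be positive, and the result is scaled to
unit variance.

**aCompCor.** `compute_acompcor()` extracts the 10 first principal
components of the variance-normalized noise pool (the stand-in for
combined white-matter and CSF voxel series). Ten components is the
standard anatomical CompCor operating point. If the pool has lower rank,
the available components are returned with a flag rather than an error.

**Framewise displacement.** `framewise_displacement()` converts rotations
to arc length on a 50 mm sphere, the radius used by the convention this
summary follows. Exclusion thresholds (mean interframe motion ≥ 0.3 mm or
0.3°, maximum ≥ 1 mm or 1°) are inclusive: a subject exactly at threshold
is excluded.

**QC statistic.** `qc_fd_signal_coupling()` correlates framewise
displacement with a DVARS-like index (frame-to-frame root mean square of
the signal derivative across nodes) before and after nuisance regression.
Effective noise correction should shrink this coupling toward zero, which
is exactly what the synthetic-data tests assert (directionally, not at a
fixed value, because the coupling magnitude depends on the planted
contamination strength).

## Connectomes

`build_connectome()` computes every edge as the partial correlation of
two node eigenvariates given the same 16 nuisance covariates (10 aCompCor
components + 6 motion parameters). Two readings of "partial correlation"
were possible: conditioning on the nuisance covariates only, or a full
joint precision over all 246 nodes plus covariates. The covariate-only
reading is implemented, because estimating a 246-node precision matrix
from ~295 frames would be ill-posed without a regularizer that the
methodology never mentions. An intercept is always included in the
residualization (filtered series are not guaranteed centered), the
diagonal is stored as zero so self-edges can never be selected as
features, and the edge order is fixed package-wide by `edge_index_map()`
(lexicographic upper triangle, 1-based indices in keeping with R
convention; 246 nodes give 30,135 edges).

## Cognitive labeling

`zscore_tests()` scores each of 8 tests (2 per domain:
attention/working-memory, executive, visuospatial/visuoperceptual,
memory) against the HC mean and SD, oriented so higher is better.
`expected_scores()` fits, per test, a least-squares regression of z on
age, sex (coded 0/1) and education in the HC group, and predicts every
subject's expected score. `classify_mci()` implements the level-I
criterion: a deficit is `expected − actual ≥ 1.5` (the margin is read
literally as a gap relative to the demographically expected score, the
more conservative of the two possible readings, and the boundary is
inclusive); MCI requires two deficits in one domain or deficits in two
domains. Missing scores make a subject unclassifiable — imputation would
silently change labels, so none is performed. `composite_scores()`
averages actual-minus-expected per domain.

## Stability selection

`rlr_select()` repeats, `n_iterations` = 200 times: draw a stratified 75%
subsample, standardize features within it, randomize each feature's
penalty by a factor drawn from {weakness, 1} with weakness = 0.5 (the
randomized-lasso construction; the randomization can be disabled), fit an
L1-penalized logistic regression, and record the nonzero coefficients.
The per-edge score is the selection frequency; `selected_edges()` keeps
scores ≥ 0.25.

Two constants here are genuinely unpublished and are therefore exposed
as configuration with documented defaults rather than presented as "the"
values: the base inverse-regularization strength (`base_c = 1`, giving
per-sample penalty λ = 1/(C·n), the parameterization used by the
reference implementation of this selector) and the selection threshold
(0.25, the selector's historical default). Tests treat both as
parameters.

A behavior worth knowing: when planted effects are very strong, the
planted edges become nearly collinear *across subjects* (each is almost a
copy of the group indicator), and an L1 fit needs only a few of them to
separate the classes. Selection frequencies then concentrate on a subset
of the true edges no matter how many iterations are run — strengthening
an effect can *reduce* the completeness of consensus recovery. The
parameter-recovery tests therefore use moderate-length series (120
frames), where per-edge estimation noise keeps the planted features
distinguishable; this is also the more realistic regime.

## Classification

`loocv_pipeline()` runs the outer LOOCV: for every held-out subject and
every repeat, stability selection and cost tuning see only the remaining
subjects. The SVM is linear with class weights n/(2·n_c) (the standard
balanced scheme for "inversely proportional to class frequencies"), and
the cost C is tuned by an inner LOOCV over the grid 10⁻³…10², ties going
to the smallest (most regularized) C. Decision values from different
outer folds are pooled into one ROC per repeat — standard LOOCV practice
— and accuracy/AUC are summarized as mean ± SD over repeats. An empty
selection falls back to the 10 highest-scoring edges and flags the fold,
keeping the pipeline total on adversarial inputs.

`consensus_funnel()` tallies the tiers: selected ever; selected in all
repeats of at least one training set; selected by ≥ 80% of training sets
in every repeat (the consensus tier used for the final model); and, per
subject, the edges selected in ≥ 80% of that subject's repeats (the fixed
feature sets of null model 1). All thresholds are inclusive.

`fit_final_and_validate()` trains one class-weighted SVM on the full
training sample restricted to the consensus edges and classifies an
independent validation sample. How C was chosen for this final model is
unstated in the source methodology; nested LOOCV on the full training
sample is used, mirroring the inner procedure.

## Permutation inference

All permutation p-values use p = (b+1)/(m+1), which is unbiased under
exchangeability and can never return zero. Two-tailed extremity is
distance from a stated center (zero for signed statistics, the null mean
for counts).

The three classification null models differ in what is repeated per
permutation:

* **Null model 1** reshuffles the patient labels but keeps each subject's
  selected feature set (and the observed run's cost) fixed — it tests the
  SVM given the features.
* **Null model 2** reruns stability selection inside every training fold
  at every reshuffle — it tests the whole funnel. The held-out subject
  never enters selection, also under permutation; without that guard the
  null would be optimistically biased by selection leakage, and its mean
  AUC would not sit at 0.5.
* **Null model 3** keeps the labels but redraws the *location* of the
  feature edges uniformly from the edge universe and revalidates — it
  tests whether the specific edges matter.

C is re-tuned only in null model 2 (where the whole procedure is
repeated); null models 1 and 3 reuse the observed model's tuning, which
mirrors what was and was not repeated in the modeled procedure.

`perm_group_mean_test()` permutes group labels around a one-way F;
note that with two groups the complementary assignment reproduces the
observed F exactly, so the attainable p floor is ~2/(m+1).
`perm_regression()` uses Freedman–Lane residual permutation — the
methodology names only "the Monte Carlo method", so a standard,
well-calibrated choice was needed and is documented here. BH-FDR comes
from `stats::p.adjust` and is cross-checked in the tests against an
exhaustive step-up search.

## Network-based statistics

`nbs()` thresholds edgewise one-way F statistics (primary threshold
F = 11), forms connected components on the graph whose vertices are atlas
nodes and edges the suprathreshold edges (isolated suprathreshold edges
are size-1 components), and compares each component's edge count with the
permutation distribution of the maximal component size. Components are
significant at α = 0.0167 (5% Bonferroni-adjusted for the three group
contrasts); if nothing is significant at the primary threshold the
analysis reruns at the liberal thresholds 6–10 and reports every run.
Component size is measured in edges (node counts are also emitted)
because that is how such components are conventionally reported.

`regional_overrepresentation()` labels edges by the unordered pair of
region categories of their endpoints and compares observed per-pair
counts with draws of equally many edges from the universe. The synthetic
annotation assigns eight categories (frontal, temporal, medial temporal,
insula, cingulate, parietal, occipital, subcortical) in proportions
roughly matching a 246-node cortical/subcortical parcellation; the
category set is data, not a constant, since real parcellations differ.

## The synthetic cohort generator

`generate_cohort()` draws each subject's node series from a zero-mean
multivariate Gaussian. The population correlation matrix is a
block-modular base — 7 contiguous communities, within-block r = 0.3,
between-block r = 0.05 — shared by HC and PD-nonMCI; the PD-MCI matrix
adds the planted deltas (default: 21 edges placed uniformly over the
network, 16 at −0.35 and 5 at +0.35, emulating the weakened/strengthened
split of the discriminating edges and comfortably inside the ±1
feasibility bound). Any indefiniteness after planting is repaired
deterministically by clipping eigenvalues at 10⁻⁶ and renormalizing to
unit diagonal; the repaired matrices are the stored ground truth, so
convergence tests compare against what was actually planted.

Nuisance structure: 10 latent sources enter both the ROI series (scaled
by `contamination_weight = 0.6`) and the noise pool, and a framewise-
displacement-locked artifact (scale `motion_coupling = 0.8`) enters both
— motion affects all tissue classes, which is exactly why aCompCor
components can remove motion-locked variance. Motion traces are AR(1)
increment processes with occasional spikes, scaled so mean interframe
translation ≈ 0.08 mm and rotation ≈ 0.035°, the magnitudes typical of
the emulated cohorts. Neuropsychological scores are a linear
age/sex/education trend plus a per-subject domain latent plus noise, with
PD-MCI domain latents shifted down by (0, 1.7, 1.3, 0.9) HC-SD units for
attention/executive/visuospatial/memory — the composite-score gaps
observed between the emulated patient groups. Demographics and clinical
covariates (age, education, sex ratio, disease duration, LEDD, UPDRS,
Hoehn–Yahr stages) are drawn from the emulated group-wise summaries.

What the generator does **not** emulate: hemodynamics and voxel-level
imaging (series are node-level by construction), spatial autocorrelation
within regions, between-subject variation of the connectivity matrix
beyond sampling noise (every subject of a group shares one population
matrix), non-Gaussian marginals, and scanner drift. Passing tests
therefore demonstrate the pipeline's statistical machinery — leakage-free
cross-validation, calibrated nulls, recoverable planted structure — not
performance on real fMRI.

Ground truth (group labels, planted edges, target matrices) is stored
alongside, never inside, the pipeline inputs, and `write_cohort()` omits
it from the on-disk layout, so no stage can accidentally consume it.

## Numerical choices and degenerate inputs

* Feature standardization uses population (1/n) SDs; zero-variance
  columns become all-zero instead of NaN and can never be selected.
* Partial correlations with rank-deficient covariates drop dependent
  columns with a warning; zero residual variance is an error (the edge is
  undefined), while degenerate nodes inside `build_connectome()` are
  flagged and their edges zeroed so one bad region does not abort a
  subject.
* L1 fits use a short 3-value λ path ending at the target penalty
  (warm-started coordinate descent is faster and more stable than a cold
  single-λ fit).
* Tie-breaks are deterministic everywhere: smallest C on tuning ties,
  ascending edge index on equal selection scores.
* Every stochastic routine takes a seed; the pipeline expands one global
  seed into fixed per-stage offsets so toggling a stage does not change
  the draws of the others.

## Problem sizes used by the tests and the acceptance script

Full-scale settings (200 selection iterations, 10 repeats, 1000/10000
permutations, nested cost tuning, 30,135 edges) reproduce the modeled
study's configuration but are hours-scale. The packaged tests and
`scripts/acceptance.R` therefore run scaled configurations, chosen once
as representative desk-scale problem sizes and documented here:

* fixed-feature label-permutation null: 24-node cohort (276 edges),
  43 vs 27 patients, observed run with 5 repeats × 25 selection
  iterations, then 1000 permutations; scaled runs fix C = 1 instead of
  nested tuning, and the nulls reuse that C.
* full-reselection null: 20-node cohort (16-node in the test suite),
  100 label reshuffles (40 in the test suite), 50 selection iterations
  per fold (25 in the test suite).
* parameter recovery: five 32-node cohorts (496 edges), 120-frame
  series, 3 repeats × 150 selection iterations, compared against a
  30-permutation fixed-feature null band (mean + 3 SD).
* type-I calibration: 1200 replicates at 119 permutations each, so that
  p ≤ 0.05 corresponds to exactly the nominal 6/120 rejection region and
  the Monte Carlo error of the estimated rate is ~0.006.

## Known limitations

* The generator's single shared population matrix per group makes strong
  planted effects nearly collinear across subjects (see the stability-
  selection note above); real cohorts have between-subject connectivity
  variance that softens this.
* The covariate-only partial correlation is a modeling choice; a
  regularized full-precision estimate is a legitimate alternative the
  package deliberately does not implement.
* With 10 latent sources plus one motion component, the 10 retained
  aCompCor components cannot span the full nuisance space; a small
  residual contamination remains, as it would in practice.
* LOOCV has high variance; the repeat structure quantifies only the
  selection/tuning variability, not the fold-structure variance itself.
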