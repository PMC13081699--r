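---
title: "Brain-age prediction from functional connectivity: models, simulation design, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age prediction from functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcage)
```

## The scientific problem

A brain-age model learns to predict chronological age from resting-state
functional connectivity (FC), and the residual — the brain-age gap,
`BAG = true age − predicted age` — becomes an individual index of
developmental timing. Under the maturational-lag account of reading
disorder, children who read poorly should look *younger* than they are
to such a model (positive BAG), and exceptional readers older (negative
BAG). `fcage` implements the full analysis chain needed to test that
prediction: an FC feature pipeline, a permutation ensemble of PCA +
linear support-vector regression (SVR), back-projection of model
weights to individual connections with permutation-null inference, and
group/continuous-skill inference on the BAG. Because the motivating
cohort data sit behind a data-use agreement, the package ships a
synthetic generator that reproduces the cohort's statistical structure,
so every stage is testable end to end.

## The prediction model

Features are Fisher z-transformed Pearson correlations between every
pair of parcellation ROIs, vectorized in a fixed canonical order
(pairs `(i, j)` with `i < j` by ROI id, row-major; `choose(400, 2) =
79,800` edges for a 400-ROI atlas). Reduced "reading-network" models use
only edges whose both endpoints survive a coordinate-hit cutoff
(`map_coordinates()`, `count_hits()`, `apply_cutoff()`), giving a
nested ladder of ROI sets.

One ensemble member does, in order:

1. a stratified 2:1 train-test split, drawn *within each reading group*
   (test count `floor(n_g / 3)` per group — the only rounding consistent
   with a 496/246 split of 211/338/193) so groups are proportionally
   represented on both sides;
2. PCA on the training rows only, keeping the minimal number of leading
   components reaching 95% cumulative explained variance;
3. 5-fold cross-validation, stratified by reading group, on the
   PCA-transformed training features (the component basis is fit once
   per permutation, not per fold; folds refit only the SVR);
4. a linear epsilon-insensitive SVR (`ε = 0.1` years, `C = 1`; the cost
   constant is not pinned down by the design, so it is surfaced as a
   configuration default) on the retained component scores;
5. raw predictions for the whole sample, standardized and mapped back
   to the age scale: z-score the raw predictions, multiply by the
   sample age SD, add the sample mean age.

Reading ability never enters fitting. The ensemble repeats this for
`n_permutations` independent splits (study scale 1000; tests and the
acceptance script use 20–100), then averages rescaled predictions
within participant over the permutations where that participant was
held out. Ensemble stability is the coefficient of variation (%) of
per-permutation test MAEs.

**Why rescale?** An SVR trained on noisy high-dimensional features
compresses its predictions toward the training mean. Left raw, that
shrinkage inflates MAE while leaving the *ranking* of predictions
intact; standardizing to the sample's age scale removes the scale/offset
distortion (MAE after rescaling is invariant to any affine map of the
raw predictions). Whether the standardization pool should be the test
set only or the full train+test prediction set of that permutation is
not determined by the design; `fcage` standardizes over the full
per-permutation prediction set by default, with
`rescale_scope = "test"` as the alternative.

A consequence worth knowing: under *no* signal, rescaled predictions
are forced to have the age SD while being uncorrelated with age, so the
no-signal ensemble MAE is about √2 times the error of always predicting
the mean age (`null_model_mae()`), not equal to it. The tests assert
exactly this directional behaviour; "beating the no-signal reference by
≥25%" is therefore a conservative bar for genuine signal.

## Significance machinery

* **CV significance** (`cv_significance()`): each null iteration draws
  a fresh stratified split, shuffles the training age labels
  (preserving their multiset), and repeats the PCA + 5-fold CV
  procedure; `p = (1 + #{null CV MAE ≤ observed}) / (1 + n_null)`. The
  add-one estimator means p is never exactly zero. One calibration
  caveat: when the observed value is a *mean* CV MAE over many
  permutations while each null iteration contributes a single split's
  CV MAE, the observed statistic has much lower variance than the
  nulls, and under the no-signal null the resulting p concentrates near
  the null distribution's center rather than being uniform. The p-value
  remains conservative as a significance screen, but exact uniformity
  holds only when the observed statistic is exchangeable with the null
  draws (a single split's CV MAE) — which is how the calibration suite
  tests it.
* **Edge importance** (`backproject()`, `average_coefficients()`,
  `edge_significance()`): because the model is linear, multiplying the
  SVR coefficient vector through the component matrix gives an exact
  edge-space weight vector — back-projected predictions equal direct
  predictions to machine precision, and the suite enforces agreement to
  1e-8. Edge nulls shuffle the observed coefficient values across edge
  positions 2500 times; each position's p compares the null magnitude
  landing there against the observed magnitude. For exchangeable
  shuffles this is equivalent to pooling all values into one null, which
  is why the implementation's per-position reading and the pooled
  reading coincide. The test is one-sided on |coefficient| (importance
  framing); `side = "signed"` switches to a two-sided test. Edge flags
  are deliberately uncorrected at α = .05 across all edges, matching the
  convention that ~5% of a null feature set is flagged; an FDR variant
  can be layered on by the user via the returned p-values.
* **ROI and network enrichment** (`roi_overrepresentation()`,
  `network_representation()`): significant edges are decomposed into
  their 2k endpoint slots; each of 2500 null draws resamples 2k ROIs
  uniformly with replacement from the parcellation, so a network's null
  share automatically reflects its spatial extent. ROI flags use a
  strict α = 1e-4; network tests are two-sided on the share, reusing
  the same null draws.

## BAG inference

`rm_ancova()` fits the repeated-measures ANCOVA via a multivariate
linear model with type III sums of squares: Model (within-subject),
Group (between), true age and the Group × Age interaction, plus optional
nuisance covariates (entering as between-subject main effects only;
letting covariates interact with the within-subject factor is a design
choice we deliberately avoid to keep the error strata conventional).
Age must be a covariate because whenever predictions compress the age
range, BAG correlates positively with true age purely mechanically —
the suite demonstrates this regression-to-the-mean artefact directly.
Mauchly's test assesses sphericity; when violated at .05,
Greenhouse-Geisser corrected p-values (and ε-scaled dfs) are reported
for within-subject terms. Rows missing a covariate are dropped listwise
and counted. If the bags are identical across models the within-subject
error stratum is exactly zero and the F-ratio is formally 0/0; the
implementation short-circuits these terms to `F = 0, p = 1`, which is
the scientifically correct reading (no evidence of any Model effect).

`posthoc_pairwise()` runs Bonferroni-scaled Welch comparisons;
`towre_regression()` treats reading skill continuously, reporting
standardized betas for age, TOWRE, and their interaction, with per-bin
simple-effect follow-ups (predictors re-standardized within bin, so the
per-bin betas are comparable across bins of different age variance)
when the interaction is significant. Age bins are `[6,8), [8,9.5),
[9.5,11), [11,13), [13,15), [15,21]` — left-closed/right-open with an
inclusive top, so a printed shared boundary belongs to the higher bin.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the emulated study conditions: N = 742
split 211/338/193 across poor/typical/exceptional readers
(largest-remainder apportionment reproduces these sizes exactly), ages
6–21 drawn from a truncated skew-normal slanted toward 8–12 years
(ξ = 7.5, ω = 4.2, α = 3, chosen to give a mean near 10.7 and thick
childhood mass), TOWRE subscores drawn per group from truncated normals
at the cohort's group means/SDs and rejection-sampled (cap 1000
redraws) until the composite respects that group's cutoff, and
covariates (gender, SES with ~14–25% missingness, PIQ, handedness) at
the cohort's per-group rates.

Connectivity is generated directly in z-space:

```
z(e, p) = baseline(e) + slope(e) * (effective_age(p, e) − age_ref) + N(0, sd)
```

with within-network baselines (0.35) above between-network ones (0.10),
a configurable fraction of edges carrying age slopes — within-network
Default/Cont edges strengthen (+0.02 z/yr by default), Default↔Cont
edges anticorrelate increasingly (−0.02 z/yr), and any remainder of the
developmental budget gets half-magnitude slopes of random sign — and
`age_ref` fixed at the age-range midpoint (this centres the baseline
without affecting any slope). The maturational lag δ shifts effective
age by −δ for poor readers and +δ for exceptional readers, either on
all edges or only on reading-network edges (the default scope, matching
the hypothesis that lag effects concentrate there). The true direction
and size of any group effect is genuinely unknown — the motivating
study's own group results are mixed — so δ defaults to 0 and is a free
simulation parameter, not an estimate. When the reading-edge scope is
used without an explicit ROI set, the generator deterministically takes
the lowest-id left-hemisphere Default/Cont/SalVentAttn ROIs (~7% of the
parcellation, the 27/400 ratio), mirroring the left-lateralized
composition of reading-network coordinates.

The generator does **not** simulate BOLD time series (no hemodynamics,
autocorrelation, or motion), scanner quality control, or spatially
structured noise; edges are conditionally independent given age and
group. Passing tests therefore demonstrate that the machinery recovers
structure it is pointed at under clean conditions — they do not certify
performance on real neuroimaging data, where noise is correlated and
effects are smaller.

The synthetic parcellation assigns networks in unequal fixed
proportions (Default 21%, Cont 17%, and so on, echoing real network
extents), splits ROIs evenly across hemispheres with x-coordinates
signed by hemisphere, and samples centroids uniformly in a brain-sized
box. Coordinate-to-ROI mapping uses nearest-centroid-within-radius
(12 mm default; ties broken to the lowest ROI id and flagged), standing
in for volumetric containment when no labelled template volume is
available; the interface accepts either.

## Numerical choices and degenerate inputs

* Correlations are clipped to |r| ≤ 1 − 1e-7 before `atanh`, so
  degenerate perfectly-correlated input yields a large finite z.
* Constant raw predictions rescale to the mean age (the z-score is
  undefined); constant time-series columns and all-identical feature
  matrices raise errors naming the offender.
* The retained component count is always the minimal k whose cumulative
  explained-variance ratio reaches the target (tolerance 1e-12 guards
  floating-point equality at the boundary).
* All permutation p-values use the add-one estimator and lie in (0, 1];
  flagged sets shrink monotonically as α decreases.
* Seeding: a base seed spawns one child seed per permutation (seeds are
  drawn once by `sample.int` after `set.seed(base)`), so permutation
  17 of a 1000-permutation run can be reproduced in isolation.

## Problem sizes used in tests

The test and acceptance workloads run the full pipeline at sizes a
single desk CPU handles comfortably while leaving the statistical
conclusions intact: signal recovery at n = 450 participants, 100 ROIs
(4,950 edges), 100 permutations; null calibration at 20 cohorts of
n = 60 with 200 label-shuffle nulls each; directional BAG recovery at
10 end-to-end runs of n = 240, 60 ROIs, 40 permutations with δ = 1.5
years on all edges. The study-scale defaults (N = 742, 400 ROIs, 1000
permutations, 2500 importance nulls) remain the function defaults.

## Known limitations

* The ROI-mapping radius rule is a geometric surrogate for volumetric
  parcel containment; hit counts near parcel borders will differ from a
  labelled-volume implementation.
* The RM-ANCOVA assumes the standard univariate repeated-measures error
  structure; unbalanced missingness across models is handled only by
  listwise deletion.
* Edge significance is uncorrected by design; interpret flagged-edge
  counts relative to the α × M expectation, not as familywise
  discoveries.
* Synthetic FC lacks the spatial covariance of real connectomes, so
  component counts retained by PCA on synthetic data (driven by white
  noise rank) do not mirror those on real data.
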