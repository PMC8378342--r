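---
title: "Methods: ensemble SDMs, gating, and range-change accounting in esdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SDMs, gating, and range-change accounting in esdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esdm)
```

## The modelling problem

Presence-only occurrence records tell us where a species *was seen*, not
where it is absent, and the records are spatially biased toward surveyed
areas. `esdm` follows the standard ensemble recipe for this situation:
thin the records to one per grid cell (so densely surveyed areas do not
over-represent their environments), manufacture pseudo-absences, fit many
different classifiers, keep the ones that demonstrably discriminate held-out
presences from pseudo-absences, and average them with skill-proportional
weights. Every choice in that chain is a tunable parameter here, with the
defaults set to the workflow's standard values.

## Pseudo-absences: "contrasting environmental conditions"

With only presences, the 0-class must be invented. The default strategy
draws `n = 5000` points (at cell centres, never in a presence cell) from sea
cells whose environmental vector falls *outside* the surface range envelope
of the presence data — per-predictor empirical quantile bounds
`[q, 1 − q]` with `q = 0.025`. This is the envelope-exclusion design:
pseudo-absences sit in conditions contrasting with those the species was
recorded in, which sharpens the presence/background boundary but also makes
the classification task easier than absence data would. The quantile and
the strategy (`"sre"` vs plain `"random"`) are arguments; `q = 0.025` is a
conventional default, not an estimate.

Because 82 presences against 5000 pseudo-absences is a degenerate
prevalence, the training table carries class-balanced case weights: each
class holds half the total weight (prevalence 0.5), and the weights average
1. Held-out evaluation uses unweighted counts.

## The learner zoo

Ten algorithm identifiers share one contract: `fit_sdm()` returns an object
whose `predict()` is a deterministic map from predictor vectors to
suitabilities in [0, 1].

| id | engine | defaults |
|----|--------|----------|
| GLM | binomial GLM, linear + quadratic terms | — |
| GAM | `mgcv::gam`, thin-plate smooths | `k = 4` per smooth |
| CTA | `rpart` classification tree | `cp = 0.001`, minbucket 5 |
| GBM | gradient-boosted trees (`xgboost`) | 500 rounds, eta 0.05, depth 3 |
| ANN | `nnet`, one hidden layer | size by internal 3-fold CV over {2, 4, 6, 8}, decay 0.01 |
| SRE | surface range envelope (own implementation) | `q = 0.025` |
| FDA | LDA on a natural-spline basis | 3 df per predictor |
| MARS | forward hinge-basis selection + binomial GLM | ≤ 10 hinge pairs, GCV penalty 3 |
| RF | `randomForest` | 500 trees, class-balanced per-tree sampling |
| MAXENT | penalized presence/background logistic (`glmnet`, lasso) on linear + quadratic features | λ by 5-fold `cv.glmnet` |

Notes on the in-house learners. The **SRE** is the quantile-box classifier:
suitable iff every predictor lies inside its presence-data bounds; its
per-margin coverage at `q = 0.025` is 95% by construction, so joint coverage
over six weakly correlated predictors is near `0.95^6 ≈ 0.74` — envelope
models are intentionally coarse, and they routinely fail skill gates.
**FDA** is the flexible-discriminant idea in its plainest form: expand each
predictor in a natural-spline basis, then linear discriminant analysis with
equal priors. **MARS** builds reflected hinge pairs `(max(0, x − t),
max(0, t − x))` greedily at candidate knots (inner 5%–95% quantiles),
stopping when a GCV criterion (penalty 3 per pair) stops improving, then
fits a binomial GLM on the selected basis. **MAXENT** is the
maxent-equivalent penalized logistic on presence/background data; it keeps
the artifact self-contained rather than calling an external Java engine.
The GBM default of 500 rounds at shrinkage 0.05 spans the same effective
regularisation as the slower classic 2500 × 0.01 setting; both are
overridable through `hyper = list(GBM = list(...))`.

The boosted-tree and quadratic-logistic engines ride on `xgboost` and
`glmnet` because those are the implementations a practitioner would use;
the contribution-level machinery — envelope, metrics, thresholding, gating,
weighting, importance, range change — is implemented from first principles
in this package and cross-checked in the tests against independent oracles
(O(n²) pair counting for AUC, exhaustive candidate scans for thresholds,
brute-force cell tallies for range change).

## Evaluation, gating, ensembling

`make_splits()` produces repeated stratified k-fold assignments (default
k = 5, 10 repetitions; each fit trains on 80% of rows). Per algorithm ×
repetition × fold, the withheld fold yields the TSS-maximising threshold
(candidates: midpoints between consecutive distinct scores, plus 0 and 1;
ties resolved toward the smallest threshold; scores at the threshold count
as positive), the TSS there, and the rank-based AUC with ties counted half.

Retention requires mean TSS **strictly** above 0.80 *and* mean AUC strictly
above 0.85 ("above" is read as strict). Retained algorithms are refit on
the full table and combined with weights proportional to their CV mean TSS
(AUC selectable). Refitting on all data keeps one member per algorithm and
uses every record; the CV means remain the weights, so an algorithm's
influence reflects held-out skill, not training fit. The ensemble's
binarization threshold is then the TSS-maximising threshold of the ensemble
scores on the training table, frozen and reused unchanged for all future
scenarios — future maps must not re-tune the cutoff they are compared by.

Permutation importance is `1 − cor(pred, pred_shuffled)` (10 runs, mean ±
SE over runs; SE denominator is the number of runs). Values are reported
unclamped: `1 − r` exceeds 1 when a shuffle anticorrelates the predictions.
A constant prediction vector has no defined correlation; such runs score 0
with a note. Response curves are evaluation strips: one predictor swept
across its training range, the others fixed at training means (medians
selectable).

## Range-change accounting

All percentages are relative to the *current* suitable cell count, which is
the only convention under which the table identities close exactly:
`PercLoss + PercStable = 100` and `SpeciesRangeChange = PercGain − PercLoss
= 100 · (future − current)/current`. Suitability is counted in valid cells,
not km²; on a regular lon/lat grid cell areas shrink poleward, so a
`cos(latitude)`-weighted variant is provided (`area_weighted = TRUE`) but
off by default — the identities hold under both, but cell counting is the
convention the published tables follow. Scenario shifts are additive deltas
on the dynamic layers (temperature, salinity, current velocity, ice);
depth and distance to shore are constant by assumption, and
`scenario_delta()` refuses to shift them.

## The virtual-species generator

`generate_env_stack()` emulates the qualitative structure of the real
predictor set, not any real ocean: smoothed seeded Gaussian noise (moving
Gaussian kernel, reflected edges; `smoothness` is the kernel sigma in
cells) rescaled per layer — temperature with a poleward-cooling gradient
centred on the study-area mean 22.72 °C, salinity around 34.51 PSS, current
velocity around 0.10 m/s, ice essentially zero outside the most poleward
fringe — plus a synthetic land–sea boundary from which distance to shore
(chamfer distance transform, km) and ocean depth (saturating increase with
shore distance plus independent bathymetric noise, clipped positive) are
derived. The depth–shore coupling is deliberately weak enough that all six
layers pass the |r| < 0.7 collinearity screen, as the real retained six do.

`generate_virtual_species()` computes a truth suitability per sea cell from
a niche of per-predictor responses (gaussian / logistic / flat) combined as
a weighted product with normalised exponents, then samples presence cells
by repeated Bernoulli sweeps with `p = suitability^γ` until the target
count (default 82) is reached — a presence-only observation process with no
survey bias. The default niche mirrors the intended importance structure:
distance to shore (weight 0.47) and depth (0.44) dominate; temperature
(0.23) and salinity (0.14) are moderate, current velocity weak (0.08), ice
nil. The truth binary map uses a fixed 0.5 threshold; the pipeline's
threshold is learned, never copied.

What passing the recovery tests shows — and does not. On this generator the
gated ensemble recovers the truth binary map with TSS > 0.8 and ranks the
two dominant predictors first; that validates the machinery, not the
ecology. Real occurrence data add survey bias, positional error, spatial
autocorrelation of residuals, and predictors the model never sees; none of
these are emulated, so real-data skill will be lower and importance
rankings less clean.

## Numerical and design choices

- **Collinearity screen.** "Correlation below 0.7" is applied to |r|
  (absolute value), the standard collinearity reading; selection is greedy
  in a user-supplied priority order because the historical choice among
  correlated candidates is not recoverable. Constant layers have undefined
  correlations and are reported `NA`, never 0, and never retained.
- **Grid conventions.** Cell centres at `min + (i − 0.5)·cell`, half-open
  cells on both axes (a point on the upper extent bound is outside; the
  lower bound is inside); longitudes normalised to [−180, 180).
- **Thresholding convention.** `score ≥ t` predicts presence; this only
  matters for exact ties at the threshold.
- **Seeding.** One master seed fans out via a seeded `sample.int` to
  pseudo-absence draws, split generation, per-fit seeds, and refits; any
  stage re-run with the same inputs and seed is bit-identical.
- **Degenerate inputs.** One-class training subsets, all-constant
  predictors, empty envelopes, zero current suitable area, and undefined
  confusion margins raise immediate errors naming the offender; the flat
  spline/ice case falls back to a linear basis column.
- **Problem sizes.** The recovery analyses in the test suite run on an
  80 × 80 grid with 300 presences, 5000 pseudo-absences, fivefold CV with 2
  repetitions — large enough for stable gates and importance rankings,
  small enough to iterate on. The full design (10 repetitions) is the
  package default.

## Known limitations

Full-dispersal assumption in the range accounting; no spatial-block CV (a
spatially clustered species will look better under random folds than it
should); no MESS-style extrapolation flags when projecting outside the
training envelope; additive uniform deltas cannot produce spatially
heterogeneous climate signals (a per-cell delta matrix is accepted, but the
built-in scenarios are uniform); raster I/O is the plain-text ASCII grid
format, single band, geographic coordinates only.
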