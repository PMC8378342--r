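# esdm — ensemble species distribution modelling with climate-scenario range projection

`esdm` fits habitat-suitability models for a species from presence-only
records and gridded environmental layers, the standard problem faced by
marine ecologists asking where a species can live now and how much of that
range survives a changing climate. It was built around the workflow used for
coastal marine megafauna (the motivating case is a warm-water, nearshore,
shallow-habitat dolphin modelled from ~82 usable occurrence records and six
marine predictors: mean temperature, salinity, current velocity, ice
thickness, ocean depth, and distance to shore), but every stage is generic.

## The method

Given presences `P` and an environmental stack on a regular lon/lat grid:

1. **Thinning and extent filtering.** At most one record per grid cell, then
   a half-open study-extent filter (default 50°E–180°E, 50°S–50°N at 5
   arc-minutes).
2. **Pseudo-absences.** Without true absences, `n = 5000` background points
   are sampled from sea cells in *contrasting environmental conditions*:
   outside the presence surface range envelope (per-predictor quantile
   bounds at `q = 0.025`). Classes are weight-balanced (prevalence 0.5).
3. **Learner zoo.** Ten algorithms under one fit/predict contract — GLM,
   GAM, CTA, GBM, ANN, SRE, FDA, MARS, RF, MAXENT — each mapping a predictor
   vector to a suitability in [0, 1].
4. **Evaluation.** Stratified fivefold cross-validation with 10 repetitions
   (each fit trains on 80%, scores the withheld 20%). Per fold:
   `TSS = sensitivity + specificity − 1` at the TSS-maximising threshold,
   and rank-based (Mann–Whitney) AUC.
5. **Gating and ensembling.** Algorithms with mean `TSS > 0.80` **and**
   mean `AUC > 0.85` are retained, refit on the full table, and combined as
   a weighted average with weights `w_i = TSS_i / Σ TSS_j`.
6. **Binarization.** Continuous maps become suitable/unsuitable at the
   ensemble's TSS-maximising training threshold, frozen and reused for
   every future scenario.
7. **Importance and response.** Permutation importance
   `1 − cor(pred, pred_with_predictor_shuffled)` (mean ± SE over 10 runs),
   and evaluation-strip response curves.
8. **Range change.** Future stacks are the current stack plus additive
   per-predictor scenario deltas (eight RCP × horizon scenarios built in;
   depth and distance to shore stay constant). For each scenario, with all
   percentages relative to the current suitable cell count:

   ```
   PercLoss   = 100 · lost / current     PercGain = 100 · gained / current
   PercStable = 100 · stable / current   SpeciesRangeChange = PercGain − PercLoss
   ```

   so `PercLoss + PercStable = 100` and `SpeciesRangeChange` equals
   100 × (future − current) / current suitable area.

A built-in virtual-species generator (smooth spatially autocorrelated
fields over a synthetic land–sea template, a configurable niche, Bernoulli
presence sampling) makes the whole pipeline testable with known ground
truth and no data downloads.

## Worked example

```r
library(esdm)

g   <- grid_spec(100, 140, -20, 20, cell_size = 0.5)        # 80 x 80 cells
stk <- generate_env_stack(g, seed = 11)                     # T Sal CV Ice Depth Dshore
sp  <- generate_virtual_species(stk, n_presences = 300, seed = 11)

fit <- esdm(sp$presences, stk, n_pseudo = 5000, repetitions = 2, seed = 101)
fit
#> Ensemble species distribution model
#>   training: 300 presences, 5000 pseudo-absences, 6 predictors
#>   CV design: 5-fold x 2 repetitions; gates TSS > 0.80, AUC > 0.85
#>   retained: GLM, GAM, CTA, GBM, ANN, FDA, MARS, RF, MAXENT
#>   binarization threshold 0.4524 (training TSS 0.956)
```

Only the envelope-box SRE misses the gates (mean TSS 0.766, AUC 0.883 —
presence-range boxes rarely compete with fitted classifiers). The niche of
this virtual species is dominated by depth and distance to shore, and the
fitted ensemble recovers that ranking:

```r
variable_importance(fit, seed = 1)
#>   predictor importance      se
#>       Depth     0.789  0.0059
#>      Dshore     0.331  0.0037
#>          CV     0.027  0.0004
#>         Sal     0.010  0.0002
#>           T     0.008  0.0002
#>         Ice     0.001  0.0000
```

Projection under the built-in scenario shifts, binarized at the frozen
threshold:

```r
rc <- range_change_table(fit$ensemble, stk, threshold = fit$threshold)
round(rc[, c("RCP45_2050s", "RCP85_2100s")], 3)
#>                    RCP45_2050s RCP85_2100s
#> PercLoss                82.489      88.987
#> PercGain                 0.000       0.000
#> PercStable              17.511      11.013
#> SpeciesRangeChange     -82.489     -88.987
```

Each column reads: of the currently suitable cells, `PercLoss`% become
unsuitable, `PercStable`% remain, `PercGain`% of that area is newly gained
elsewhere, and `SpeciesRangeChange` is the net percentage change of the
suitable range. The identities `PercLoss + PercStable = 100` and
`change = gain − loss` hold in every column.

For a file-driven run (`simulate` → `fit` → `project` writing CSV/ASC/JSON
artifacts), see `read_run_config()`, `cmd_simulate()`, `cmd_fit_evaluate()`
and `cmd_project()`, or the wrapper script
`inst/cli/esdm-pipeline.R <simulate|fit|project|all> --config cfg.yml`.

## Limitations

- Cell-count (not geodesic-area) accounting by default; a cos(latitude)
  weighting is available via `range_change(..., area_weighted = TRUE)`.
- Full-dispersal assumption: a newly suitable cell counts as gained
  wherever it is.
- Uniform additive scenario deltas; no AOGCM spatial structure.
- No spatial-block cross-validation; folds are stratified by class only.
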