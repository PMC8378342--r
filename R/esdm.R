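# The top-level fitted-model interface: esdm() runs the full ensemble SDM
# workflow and returns a classed object with the usual S3 methods.

#' Fit a metric-gated weighted ensemble species distribution model
#'
#' Runs the complete workflow on presence records and an environmental
#' stack: grid-thins and extent-filters the presences, draws pseudo-absences
#' in contrasting environmental conditions, builds the class-balanced
#' training table, cross-validates the ten-algorithm learner zoo under a
#' repeated stratified k-fold design, retains the algorithms whose mean TSS
#' and AUC clear the gates, refits each retained algorithm on the full
#' table, combines them into a metric-proportional weighted-average
#' ensemble, freezes the ensemble's TSS-maximising binarization threshold,
#' and projects the current suitability map.
#'
#' One master seed fans out deterministically to pseudo-absence sampling,
#' split generation and every stochastic learner, so a run is exactly
#' reproducible.
#'
#' @param presences a [presence_set()] (or data.frame with `lon`, `lat`).
#' @param stack the current-period [layer_stack()].
#' @param algorithms algorithm ids to consider; default all ten.
#' @param n_pseudo number of pseudo-absence points; default 5000.
#' @param pa_strategy pseudo-absence strategy, `"sre"` or `"random"`.
#' @param envelope_quantile envelope tail mass for the `"sre"` strategy.
#' @param k,repetitions cross-validation design; defaults 5 folds, 10
#'   repetitions.
#' @param tss_min,auc_min retention gates on CV means; defaults 0.80, 0.85.
#' @param weighting_metric `"TSS"` (default) or `"AUC"` ensemble weighting.
#' @param thin thin presences to one per grid cell first? default `TRUE`.
#' @param hyper per-algorithm hyperparameter overrides.
#' @param seed master seed.
#' @param verbose progress messages.
#' @return an object of class `esdm`; see [predict.esdm()],
#'   [summary.esdm()], [plot.esdm()], [variable_importance()].
#' @examples
#' \donttest{
#' g <- grid_spec(100, 130, -15, 15, cell_size = 1)
#' stk <- generate_env_stack(g, seed = 7)
#' sp <- generate_virtual_species(stk, n_presences = 60, seed = 7)
#' fit <- esdm(sp$presences, stk, algorithms = c("GLM", "CTA", "SRE"),
#'             n_pseudo = 500, repetitions = 2, seed = 7)
#' fit
#' }
#' @export
esdm <- function(presences, stack, algorithms = sdm_algorithms(),
                 n_pseudo = 5000, pa_strategy = c("sre", "random"),
                 envelope_quantile = 0.025, k = 5, repetitions = 10,
                 tss_min = 0.80, auc_min = 0.85,
                 weighting_metric = c("TSS", "AUC"), thin = TRUE,
                 hyper = list(), seed = 1L, verbose = FALSE) {
  cl <- match.call()
  pa_strategy <- match.arg(pa_strategy)
  weighting_metric <- match.arg(weighting_metric)
  if (!inherits(presences, "presence_set"))
    presences <- presence_set(presences$lon, presences$lat)

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  wrap <- if (verbose) identity else suppressMessages
  if (thin) presences <- wrap(thin_to_grid(presences, stack$grid))
  presences <- wrap(filter_extent(presences, stack$grid))
  bg <- generate_pseudo_absences(stack, presences, n = n_pseudo,
                                 strategy = pa_strategy,
                                 envelope_quantile = envelope_quantile,
                                 seed = seeds[1L])
  table <- wrap(build_training_table(stack, presences, bg))
  splits <- make_splits(table, k = k, repetitions = repetitions,
                        seed = seeds[2L])
  records <- evaluate_sdms(table, algorithms = algorithms, seed = seeds[3L],
                           hyper = hyper, splits = splits, verbose = verbose)
  gate <- aggregate_and_gate(records, tss_min = tss_min, auc_min = auc_min)
  if (!length(gate$retained))
    stop("no algorithm cleared the retention gates (mean TSS > ", tss_min,
         " and mean AUC > ", auc_min, ")")

  set.seed(seeds[4L])
  refit_seeds <- sample.int(.Machine$integer.max - 1L, length(gate$retained))
  members <- stats::setNames(lapply(seq_along(gate$retained), function(i) {
    alg <- gate$retained[i]
    fit_sdm(alg, table, seed = refit_seeds[i],
            hyper = if (is.null(hyper[[alg]])) list() else hyper[[alg]])
  }), gate$retained)

  metric_col <- if (weighting_metric == "TSS") "tss" else "auc"
  scores <- stats::setNames(
    gate$means[[metric_col]][match(gate$retained, gate$means$algorithm)],
    gate$retained)
  ens <- build_ensemble(members, scores, metric = weighting_metric)

  train_pred <- predict(ens, table)
  opt <- optimal_threshold(train_pred, table$occ)

  structure(list(call = cl, presences = presences, background = bg,
                 table = table, splits = splits, records = records,
                 means = gate$means, retained = gate$retained,
                 ensemble = ens, threshold = opt$threshold,
                 training_tss = opt$tss,
                 current = project_sdm(ens, stack),
                 stack = stack, seed = seed,
                 gates = c(tss_min = tss_min, auc_min = auc_min)),
            class = "esdm")
}

#' @export
print.esdm <- function(x, ...) {
  cat("Ensemble species distribution model\n")
  cat(sprintf("  training: %d presences, %d pseudo-absences, %d predictors\n",
              sum(x$table$occ == 1), sum(x$table$occ == 0),
              length(attr(x$table, "predictors"))))
  cat(sprintf("  CV design: %d-fold x %d repetitions; gates TSS > %.2f, AUC > %.2f\n",
              max(x$splits), ncol(x$splits), x$gates["tss_min"],
              x$gates["auc_min"]))
  cat(sprintf("  retained: %s\n", paste(x$retained, collapse = ", ")))
  cat(sprintf("  binarization threshold %.4f (training TSS %.3f)\n",
              x$threshold, x$training_tss))
  invisible(x)
}

#' Summarise a fitted ensemble SDM
#'
#' @param object an [esdm()] fit.
#' @param ... unused.
#' @return a `summary.esdm` with the per-algorithm CV means, retention
#'   flags, ensemble weights and threshold.
#' @export
summary.esdm <- function(object, ...) {
  m <- object$means
  m$weight <- object$ensemble$weights[match(m$algorithm,
                                            names(object$ensemble$weights))]
  m$weight[is.na(m$weight)] <- 0
  structure(list(means = m[order(-m$tss), ], threshold = object$threshold,
                 training_tss = object$training_tss,
                 metric = object$ensemble$metric,
                 gates = object$gates), class = "summary.esdm")
}

#' @export
print.summary.esdm <- function(x, ...) {
  cat(sprintf("Per-algorithm cross-validation means (gates: TSS > %.2f, AUC > %.2f):\n",
              x$gates["tss_min"], x$gates["auc_min"]))
  df <- x$means
  df$tss <- round(df$tss, 3); df$auc <- round(df$auc, 3)
  df$weight <- round(df$weight, 3)
  print(df, row.names = FALSE)
  cat(sprintf("Ensemble: %s-proportional weights; binarization threshold %.4f (training TSS %.3f)\n",
              x$metric, x$threshold, x$training_tss))
  invisible(x)
}

#' Predict from a fitted ensemble SDM
#'
#' @param object an [esdm()] fit.
#' @param newdata a predictor data.frame, or a [layer_stack()] to project
#'   onto; default the training stack.
#' @param type `"suitability"` (continuous, default) or `"binary"` (using
#'   the frozen TSS-maximising threshold).
#' @param ... unused.
#' @return a numeric vector for data.frame input; a `suitability_map` or
#'   `binary_map` for stack input.
#' @export
predict.esdm <- function(object, newdata = NULL,
                         type = c("suitability", "binary"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$stack
  if (inherits(newdata, "layer_stack")) {
    map <- project_sdm(object$ensemble, newdata)
    if (type == "binary") binarize(map, object$threshold) else map
  } else {
    p <- predict(object$ensemble, newdata)
    if (type == "binary") as.numeric(p >= object$threshold) else p
  }
}

#' Ensemble weights of a fitted ensemble SDM
#'
#' @param object an [esdm()] fit.
#' @param ... unused.
#' @return named numeric vector of metric-proportional member weights
#'   (sum 1).
#' @export
coef.esdm <- function(object, ...) object$ensemble$weights

#' Permutation variable importance of a fitted ensemble SDM
#'
#' @param object an [esdm()] fit (or any model accepted by
#'   [permutation_importance()]).
#' @param n_perm permutation runs; default 10.
#' @param seed RNG seed.
#' @return importance table (see [permutation_importance()]).
#' @export
variable_importance <- function(object, n_perm = 10, seed = 1L) {
  model <- if (inherits(object, "esdm")) object$ensemble else object
  table <- if (inherits(object, "esdm")) object$table else
    stop("supply an esdm fit, or call permutation_importance() directly")
  permutation_importance(model, table, n_perm = n_perm, seed = seed)
}

#' Plot a suitability or binary map
#'
#' @param x a `suitability_map` or `binary_map`.
#' @param main title; defaults to the scenario label.
#' @param ... passed to [graphics::image()].
#' @export
plot.suitability_map <- function(x, main = x$scenario_label, ...) {
  g <- x$grid
  lon <- g$lon_min + (seq_len(g$n_cols) - 0.5) * g$cell_size
  lat <- g$lat_min + (seq_len(g$n_rows) - 0.5) * g$cell_size  # ascending
  z <- t(x$values)[, rev(seq_len(g$n_rows)), drop = FALSE]    # [lon, lat asc]
  graphics::image(lon, lat, z, xlab = "lon", ylab = "lat", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' @export
#' @rdname plot.suitability_map
plot.binary_map <- plot.suitability_map

#' Plot the current suitability map of a fitted ensemble SDM
#'
#' @param x an [esdm()] fit.
#' @param type `"suitability"` or `"binary"`.
#' @param points overlay the training presences?
#' @param ... passed to the map plot.
#' @export
plot.esdm <- function(x, type = c("suitability", "binary"), points = TRUE,
                      ...) {
  type <- match.arg(type)
  map <- if (type == "binary") binarize(x$current, x$threshold) else x$current
  plot(map, ...)
  if (points)
    graphics::points(x$presences$lon, x$presences$lat, pch = 16, cex = 0.5)
  invisible(x)
}
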