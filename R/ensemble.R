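# Weighted-average ensembling, permutation variable importance, response
# curves.

#' Build a weighted-average ensemble
#'
#' Combines retained member models with weights proportional to their
#' evaluation scores (`weight_i = score_i / sum(score_j)`); the ensemble
#' prediction is the weighted mean of the member predictions, so it always
#' lies within the members' prediction range.
#'
#' @param models named list of fitted `sdm_model` objects (typically one per
#'   retained algorithm, refit on the full table).
#' @param scores named numeric vector of evaluation scores (e.g. CV mean TSS
#'   per algorithm) covering all members.
#' @param metric label of the weighting metric; `"TSS"` (default) or
#'   `"AUC"`.
#' @return an object of class `sdm_ensemble` with members and normalised
#'   weights.
#' @export
build_ensemble <- function(models, scores, metric = c("TSS", "AUC")) {
  metric <- match.arg(metric)
  if (!length(models)) stop("need at least one retained model")
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "algorithm")
  missing <- setdiff(names(models), names(scores))
  if (length(missing))
    stop("no score for member(s): ", paste(missing, collapse = ", "))
  s <- scores[names(models)]
  if (all(s <= 0)) stop("all metric scores are <= 0; cannot form weights")
  if (any(s < 0)) s[s < 0] <- 0
  w <- s / sum(s)
  structure(list(members = models, weights = w, metric = metric),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble: %d members, %s-proportional weights\n",
              length(x$members), x$metric))
  print(round(x$weights, 4))
  invisible(x)
}

#' Predict suitability from an ensemble
#'
#' @param object an [build_ensemble()] result.
#' @param newdata data.frame covering every member's predictors.
#' @param ... unused.
#' @return weighted-mean suitability in `[0, 1]`.
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  p <- rep(0, nrow(newdata))
  for (i in seq_along(object$members))
    p <- p + object$weights[[i]] * predict(object$members[[i]], newdata)
  pmin(pmax(p, 0), 1)
}

model_predictors <- function(model) {
  if (inherits(model, "sdm_ensemble"))
    unique(unlist(lapply(model$members, `[[`, "all_predictors")))
  else model$all_predictors
}

#' Permutation variable importance
#'
#' Shuffles one predictor column (seeded) and measures how much the
#' predictions decorrelate from the originals: importance =
#' 1 - Pearson(pred_full, pred_shuffled), averaged over `n_perm` runs with
#' its standard error. A predictor the model ignores scores 0; a dominant
#' predictor scores near 1. Values are reported unclamped (1 - r can exceed
#' 1 when r < 0). If either prediction vector is constant the correlation is
#' undefined and the importance of that run is recorded as 0.
#'
#' @param model an `sdm_model` or `sdm_ensemble`.
#' @param table data at which to evaluate (typically the training table).
#' @param predictors predictors to assess; default all of the model's.
#' @param n_perm permutation runs per predictor; default 10.
#' @param seed RNG seed.
#' @return data.frame with `predictor`, `importance` (mean) and `se`.
#' @export
permutation_importance <- function(model, table, predictors = NULL,
                                   n_perm = 10, seed = 1L) {
  d <- as.data.frame(table)
  if (is.null(predictors)) predictors <- model_predictors(model)
  p0 <- predict(model, d)
  set.seed(seed)
  rows <- lapply(predictors, function(pr) {
    imp <- vapply(seq_len(n_perm), function(i) {
      ds <- d
      ds[[pr]] <- ds[[pr]][sample.int(nrow(ds))]
      p1 <- predict(model, ds)
      if (stats::sd(p0) == 0 || stats::sd(p1) == 0) return(0)
      1 - stats::cor(p0, p1)
    }, 0)
    data.frame(predictor = pr, importance = mean(imp),
               se = stats::sd(imp) / sqrt(n_perm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$importance), ]
}

#' Response curve along one predictor
#'
#' Varies the chosen predictor over an evenly spaced grid across its
#' training range while holding every other predictor at its training mean
#' (or median), and records the predicted suitability — the classic
#' evaluation-strip response curve.
#'
#' @param model an `sdm_model` or `sdm_ensemble`.
#' @param table training table providing the ranges and conditioning values.
#' @param predictor predictor to vary.
#' @param n_points grid resolution; default 100.
#' @param fixed_at `"mean"` (default) or `"median"` conditioning.
#' @return data.frame of class `response_curve` with columns `predictor`,
#'   `x`, `suitability`.
#' @export
response_curve <- function(model, table, predictor, n_points = 100,
                           fixed_at = c("mean", "median")) {
  fixed_at <- match.arg(fixed_at)
  d <- as.data.frame(table)
  preds <- model_predictors(model)
  if (!predictor %in% preds) stop("unknown predictor: ", predictor)
  centre <- vapply(d[preds], if (fixed_at == "mean") mean else stats::median, 0)
  grid <- seq(min(d[[predictor]]), max(d[[predictor]]), length.out = n_points)
  nd <- as.data.frame(as.list(centre))[rep(1L, n_points), , drop = FALSE]
  nd[[predictor]] <- grid
  structure(data.frame(predictor = predictor, x = grid,
                       suitability = predict(model, nd)),
            class = c("response_curve", "data.frame"))
}

#' @export
plot.response_curve <- function(x, ...) {
  graphics::plot(x$x, x$suitability, type = "l", xlab = x$predictor[1L],
                 ylab = "suitability", ylim = c(0, 1), ...)
  invisible(x)
}
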