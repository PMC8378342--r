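# Surface range envelope (BIOCLIM-style) model, built from first principles.

#' Fit a surface range envelope
#'
#' Computes per-predictor bounds as the empirical `[q, 1 - q]` quantiles of
#' the presence data (linear-interpolation quantile definition, R type 7).
#' With `quantile = 0` the envelope is the min/max box.
#'
#' @param presence_predictors data.frame (or matrix) of predictor values at
#'   presence points only; at least two rows.
#' @param quantile per-margin tail mass in `[0, 0.5)`; default 0.025.
#' @return an object of class `sre_envelope` with `lower`, `upper` and
#'   `quantile`.
#' @export
sre_fit <- function(presence_predictors, quantile = 0.025) {
  if (quantile < 0 || quantile >= 0.5)
    stop("quantile must lie in [0, 0.5)")
  x <- as.data.frame(presence_predictors)
  if (nrow(x) < 2L) stop("need at least two presence rows")
  if (!all(vapply(x, is.numeric, TRUE))) stop("predictors must be numeric")
  lower <- vapply(x, stats::quantile, 0, probs = quantile, names = FALSE)
  upper <- vapply(x, stats::quantile, 0, probs = 1 - quantile, names = FALSE)
  structure(list(lower = lower, upper = upper, quantile = quantile,
                 predictors = names(x)),
            class = "sre_envelope")
}

#' @export
print.sre_envelope <- function(x, ...) {
  cat(sprintf("sre_envelope (q = %g):\n", x$quantile))
  print(data.frame(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Classify points against an envelope
#'
#' A point is suitable (1) iff *every* predictor lies within its
#' `[lower, upper]` bounds inclusive; otherwise unsuitable (0).
#'
#' @param envelope an [sre_fit()] result.
#' @param x data.frame (or single named vector) covering all envelope
#'   predictors.
#' @return numeric vector of 0/1 suitability values.
#' @export
sre_predict <- function(envelope, x) {
  if (!is.data.frame(x)) x <- as.data.frame(as.list(x))
  missing <- setdiff(envelope$predictors, names(x))
  if (length(missing))
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  inside <- rep(TRUE, nrow(x))
  for (p in envelope$predictors) {
    inside <- inside & x[[p]] >= envelope$lower[[p]] &
      x[[p]] <= envelope$upper[[p]]
  }
  as.numeric(inside)
}
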