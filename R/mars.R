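# Compact additive MARS-style learner: forward selection of reflected hinge
# pairs (knots at training quantiles) under a GCV criterion, then a binomial
# GLM on the selected basis.

hinge_basis <- function(X, terms) {
  if (!length(terms)) return(matrix(0, nrow(X), 0))
  cols <- lapply(terms, function(tm) {
    v <- X[[tm$var]]
    cbind(pmax(0, v - tm$knot), pmax(0, tm$knot - v))
  })
  do.call(cbind, cols)
}

fit_mars <- function(X, y, w, hp) {
  n <- nrow(X)
  knots <- lapply(X, function(v) {
    q <- unique(stats::quantile(v, probs = seq(0.05, 0.95,
                                               length.out = hp$n_knots)))
    q[q > min(v) & q < max(v)]
  })
  terms <- list()
  B <- matrix(1, n, 1)  # intercept
  gcv <- function(rss, nterms) {
    # effective parameters: columns + smoothing penalty per hinge pair
    cpar <- ncol_safe(nterms) + hp$penalty * nterms
    rss / (n * (1 - cpar / n)^2)
  }
  ncol_safe <- function(nterms) 1 + 2 * nterms
  cur_rss <- wrss(B, y, w)
  cur_gcv <- gcv(cur_rss, 0)
  repeat {
    if (length(terms) >= hp$max_pairs) break
    if (ncol(B) + 2 >= 0.9 * n) break
    best <- NULL
    for (v in names(knots)) for (kn in knots[[v]]) {
      cand <- cbind(B, pmax(0, X[[v]] - kn), pmax(0, kn - X[[v]]))
      r <- wrss(cand, y, w)
      if (is.null(best) || r < best$rss)
        best <- list(var = v, knot = kn, rss = r)
    }
    if (is.null(best)) break
    new_gcv <- gcv(best$rss, length(terms) + 1)
    if (new_gcv >= cur_gcv) break
    terms <- c(terms, list(list(var = best$var, knot = best$knot)))
    B <- cbind(B, pmax(0, X[[best$var]] - best$knot),
               pmax(0, best$knot - X[[best$var]]))
    cur_gcv <- new_gcv
  }
  basis <- hinge_basis(X, terms)
  d <- as.data.frame(basis)
  names(d) <- if (ncol(basis)) paste0("h", seq_len(ncol(basis))) else character()
  d$occ <- y
  hcols <- setdiff(names(d), "occ")
  f <- if (length(hcols)) stats::as.formula(paste("occ ~",
                                                  paste(hcols, collapse = " + ")))
       else occ ~ 1
  d$w <- w  # weights resolved inside `data`
  glm_fit <- suppressWarnings(stats::glm(f, data = d,
                                         family = stats::binomial(),
                                         weights = w))
  list(terms = terms, glm = glm_fit, predictors = names(X))
}

# weighted residual sum of squares of the least-squares fit of y on B
wrss <- function(B, y, w) {
  f <- stats::lm.wfit(B, y, w)
  sum(w * f$residuals^2)
}

predict_mars <- function(fit, X) {
  basis <- hinge_basis(X[fit$predictors], fit$terms)
  d <- as.data.frame(basis)
  names(d) <- if (ncol(basis)) paste0("h", seq_len(ncol(basis))) else character()
  as.numeric(stats::predict(fit$glm, d, type = "response"))
}
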