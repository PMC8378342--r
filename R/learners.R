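# The ten-algorithm learner zoo behind a uniform fit/predict contract.
# Every fitted model predicts a suitability in [0, 1] from a predictor
# data.frame, deterministically given its seed.

#' The ten supported algorithm identifiers
#'
#' @return character vector: GLM, GAM, CTA, GBM, ANN, SRE, FDA, MARS, RF,
#'   MAXENT.
#' @export
sdm_algorithms <- function() {
  c("GLM", "GAM", "CTA", "GBM", "ANN", "SRE", "FDA", "MARS", "RF", "MAXENT")
}

default_hyper <- function(algorithm) {
  switch(algorithm,
    GLM    = list(),
    GAM    = list(k = 4),
    CTA    = list(cp = 0.001, minbucket = 5, maxdepth = 25),
    GBM    = list(nrounds = 500, eta = 0.05, max_depth = 3),
    ANN    = list(size = NA, sizes = c(2, 4, 6, 8), decay = 0.01, maxit = 200),
    SRE    = list(quantile = 0.025),
    FDA    = list(df = 3),
    MARS   = list(max_pairs = 10, n_knots = 9, penalty = 3),
    RF     = list(ntree = 500),
    MAXENT = list(alpha = 1, nfolds = 5),
    stop("unknown algorithm: ", algorithm))
}

#' Fit one species distribution model
#'
#' Fits a single algorithm on (a subset of) a training table under the
#' uniform contract: the result predicts an occurrence suitability in
#' `[0, 1]` for any predictor vector, deterministically given the seed.
#' Case weights from the table (class-balanced by default) are honoured by
#' every weighted learner; SRE uses only the presence rows.
#'
#' Engines: GLM = binomial GLM with linear + quadratic terms; GAM = binomial
#' [mgcv::gam()] with thin-plate smooths; CTA = [rpart::rpart()]
#' classification tree; GBM = gradient-boosted trees ([xgboost]); ANN =
#' single-hidden-layer [nnet::nnet()] with the hidden size chosen by an
#' internal 3-fold CV over `sizes`; SRE = the surface range envelope
#' ([sre_fit()]); FDA = flexible discriminant analysis as LDA on a natural
#' spline basis; MARS = adaptive regression splines (forward hinge-basis
#' selection, binomial GLM on the selected basis); RF =
#' [randomForest::randomForest()] with class-balanced per-tree sampling;
#' MAXENT = maxent-equivalent penalized presence/background logistic
#' regression on linear + quadratic features ([glmnet]).
#'
#' @param algorithm one of [sdm_algorithms()].
#' @param table a [build_training_table()] result.
#' @param rows optional integer subset of rows to train on (CV fold).
#' @param seed RNG seed for stochastic learners.
#' @param hyper named list overriding the algorithm's default
#'   hyperparameters.
#' @return an object of class `sdm_model`.
#' @export
fit_sdm <- function(algorithm, table, rows = NULL, seed = 1L, hyper = list()) {
  algorithm <- match.arg(algorithm, sdm_algorithms())
  predictors <- attr(table, "predictors")
  if (is.null(predictors)) stop("table lacks a 'predictors' attribute")
  if (is.null(rows)) rows <- seq_len(nrow(table))
  d <- as.data.frame(table)[rows, , drop = FALSE]
  hp <- utils::modifyList(default_hyper(algorithm), hyper)

  y <- d$occ
  w <- d$weight
  X <- d[, predictors, drop = FALSE]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (algorithm != "SRE" && (n1 == 0 || n0 == 0))
    stop(algorithm, ": training subset must contain both classes")
  if (algorithm == "SRE" && n1 < 2)
    stop("SRE: need at least two presence rows")
  varying <- vapply(X, function(v) stats::sd(v) > 0, TRUE)
  if (!any(varying))
    stop(algorithm, ": all predictors are constant in the training subset")
  used <- predictors[varying]

  set.seed(seed)
  fit <- switch(algorithm,
    GLM = fit_glm(X[used], y, w, used),
    GAM = fit_gam(X[used], y, w, used, hp),
    CTA = fit_cta(X[used], y, w, hp),
    GBM = fit_gbm(X[used], y, w, hp, seed),
    ANN = fit_ann(X[used], y, w, hp, seed),
    SRE = sre_fit(X[y == 1, used, drop = FALSE], quantile = hp$quantile),
    FDA = fit_fda(X[used], y, hp),
    MARS = fit_mars(X[used], y, w, hp),
    RF = fit_rf(X[used], y, hp),
    MAXENT = fit_maxent(X[used], y, w, hp, seed))

  structure(list(algorithm = algorithm, fit = fit, predictors = used,
                 all_predictors = predictors, seed = seed, hyper = hp,
                 n = nrow(d), prevalence = n1 / nrow(d)),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("sdm_model [%s]: %d training rows (prevalence %.3f), predictors: %s\n",
              x$algorithm, x$n, x$prevalence,
              paste(x$predictors, collapse = ", ")))
  invisible(x)
}

#' Predict suitability from a fitted SDM
#'
#' @param object an [fit_sdm()] result.
#' @param newdata data.frame covering the model's predictors.
#' @param ... unused.
#' @return numeric suitability vector in `[0, 1]` (SRE yields 0/1).
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing))
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "))
  X <- as.data.frame(newdata)[, object$predictors, drop = FALSE]
  p <- switch(object$algorithm,
    GLM = as.numeric(stats::predict(object$fit, X, type = "response")),
    GAM = as.numeric(mgcv::predict.gam(object$fit, X, type = "response")),
    CTA = as.numeric(stats::predict(object$fit, X, type = "prob")[, "1"]),
    GBM = predict_gbm(object$fit, X),
    ANN = as.numeric(stats::predict(object$fit$net, scale_apply(object$fit$scaling, X))),
    SRE = sre_predict(object$fit, X),
    FDA = predict_fda(object$fit, X),
    MARS = predict_mars(object$fit, X),
    RF = as.numeric(stats::predict(object$fit, X, type = "prob")[, "1"]),
    MAXENT = predict_maxent(object$fit, X))
  pmin(pmax(p, 0), 1)
}

# --- engines ----------------------------------------------------------------

quad_formula <- function(predictors, response = "occ") {
  terms <- c(predictors, sprintf("I(%s^2)", predictors))
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

fit_glm <- function(X, y, w, predictors) {
  d <- cbind(occ = y, X, w = w)  # weights resolved inside `data`
  suppressWarnings(stats::glm(quad_formula(predictors), data = d,
                              family = stats::binomial(), weights = w))
}

fit_gam <- function(X, y, w, predictors, hp) {
  d <- cbind(occ = y, X, w = w)
  # drop smooth basis dimension for predictors with few unique values
  sm <- vapply(predictors, function(p) {
    u <- length(unique(X[[p]]))
    if (u > hp$k) sprintf("s(%s, k = %d)", p, hp$k) else p
  }, "")
  f <- stats::as.formula(paste("occ ~", paste(sm, collapse = " + ")))
  suppressWarnings(mgcv::gam(f, data = d, family = stats::binomial(),
                             weights = w, method = "REML"))
}

fit_cta <- function(X, y, w, hp) {
  d <- cbind(occ = factor(y, levels = c(0, 1)), X)
  d$w <- w
  f <- stats::as.formula(paste("occ ~", paste(names(X), collapse = " + ")))
  rpart::rpart(f, data = d, weights = w, method = "class",
               control = rpart::rpart.control(cp = hp$cp,
                                              minbucket = hp$minbucket,
                                              maxdepth = hp$maxdepth,
                                              xval = 0))
}

fit_gbm <- function(X, y, w, hp, seed) {
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y, weight = w)
  params <- list(objective = "binary:logistic", eta = hp$eta,
                 max_depth = hp$max_depth, nthread = 1, seed = seed)
  bst <- xgboost::xgb.train(params = params, data = dm, nrounds = hp$nrounds,
                            verbose = 0)
  list(booster = bst, predictors = names(X))
}

predict_gbm <- function(fit, X) {
  as.numeric(stats::predict(fit$booster,
                            xgboost::xgb.DMatrix(as.matrix(X[fit$predictors]))))
}

# nnet benefits from standardised inputs; remember the scaling.
scale_fit <- function(X) {
  list(center = vapply(X, mean, 0), scale = pmax(vapply(X, stats::sd, 0), 1e-12),
       predictors = names(X))
}
scale_apply <- function(s, X) {
  out <- as.data.frame(Map(function(v, c, sc) (v - c) / sc,
                           X[s$predictors], s$center, s$scale))
  names(out) <- s$predictors
  as.matrix(out)
}

fit_ann <- function(X, y, w, hp, seed) {
  scaling <- scale_fit(X)
  Xs <- scale_apply(scaling, X)
  sizes <- hp$sizes
  size <- hp$size
  if (is.na(size)) {
    if (length(sizes) > 1L) {
      # internal 3-fold CV on AUC to pick the hidden layer size
      folds <- make_fold_vector(y, k = 3, seed = seed + 1L)
      cv_auc <- vapply(sizes, function(s) {
        aucs <- vapply(1:3, function(f) {
          tr <- folds != f
          net <- nnet::nnet(Xs[tr, , drop = FALSE], y[tr], weights = w[tr],
                            size = s, decay = hp$decay, maxit = hp$maxit,
                            entropy = TRUE, trace = FALSE)
          p <- as.numeric(stats::predict(net, Xs[!tr, , drop = FALSE]))
          if (length(unique(y[!tr])) < 2L) return(NA_real_)
          auc(p, y[!tr])
        }, 0)
        mean(aucs, na.rm = TRUE)
      }, 0)
      size <- sizes[which.max(cv_auc)]
    } else size <- sizes
  }
  set.seed(seed)
  net <- nnet::nnet(Xs, y, weights = w, size = size, decay = hp$decay,
                    maxit = hp$maxit, entropy = TRUE, trace = FALSE)
  list(net = net, scaling = scaling, size = size)
}

fit_fda <- function(X, y, hp) {
  basis <- lapply(X, function(v) {
    # fall back to a linear column when the spline knots degenerate
    # (few unique values, or heavy ties as in a mostly-zero ice layer)
    if (length(unique(v)) > hp$df)
      tryCatch(splines::ns(v, df = hp$df),
               error = function(e) matrix(v, dimnames = list(NULL, "1")))
    else matrix(v, dimnames = list(NULL, "1"))
  })
  B <- do.call(cbind, basis)
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  fit <- MASS::lda(B, grouping = factor(y, levels = c(0, 1)),
                   prior = c(0.5, 0.5))
  list(lda = fit, basis = basis, predictors = names(X))
}

predict_fda <- function(fit, X) {
  B <- do.call(cbind, Map(function(b, p) {
    v <- X[[p]]
    if (inherits(b, "ns")) stats::predict(b, v) else matrix(v)
  }, fit$basis, fit$predictors))
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  as.numeric(stats::predict(fit$lda, B)$posterior[, "1"])
}

fit_rf <- function(X, y, hp) {
  yf <- factor(y, levels = c(0, 1))
  m <- min(table(yf))
  randomForest::randomForest(X, yf, ntree = hp$ntree,
                             sampsize = c(`0` = m, `1` = m))
}

fit_maxent <- function(X, y, w, hp, seed) {
  F <- maxent_features(X)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(F, y, weights = w, family = "binomial",
                          alpha = hp$alpha, nfolds = hp$nfolds)
  list(cv = cv, predictors = names(X))
}

maxent_features <- function(X) {
  F <- cbind(as.matrix(X), as.matrix(X)^2)
  colnames(F) <- c(names(X), paste0(names(X), "_sq"))
  F
}

predict_maxent <- function(fit, X) {
  as.numeric(stats::predict(fit$cv, maxent_features(X[fit$predictors]),
                            s = "lambda.min", type = "response"))
}
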