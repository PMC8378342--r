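# Weighted-average ensembling, permutation importance, response curves.

test_that("ensemble weights are metric-proportional and predictions convex", {
  tab <- toy_table(n_per_class = 30, seed = 81)
  models <- list(GLM = fit_sdm("GLM", tab, seed = 1),
                 CTA = fit_sdm("CTA", tab, seed = 1),
                 MARS = fit_sdm("MARS", tab, seed = 1))
  ens <- build_ensemble(models, c(GLM = 0.9, CTA = 0.6, MARS = 0.5))
  expect_equal(unname(ens$weights), c(0.45, 0.30, 0.25))
  expect_equal(sum(ens$weights), 1, tolerance = 1e-9)
  # prediction equals the hand-computed weighted mean
  q <- data.frame(x1 = c(-1, 0, 2.2), x2 = c(0.3, -1, 0))
  by_hand <- 0.45 * predict(models$GLM, q) + 0.30 * predict(models$CTA, q) +
    0.25 * predict(models$MARS, q)
  expect_equal(predict(ens, q), by_hand, tolerance = 1e-12)
  # convexity: within [min, max] of member predictions everywhere
  set.seed(82)
  qq <- data.frame(x1 = rnorm(100, sd = 3), x2 = rnorm(100, sd = 3))
  members <- sapply(models, function(m) predict(m, qq))
  pe <- predict(ens, qq)
  expect_true(all(pe >= apply(members, 1, min) - 1e-12))
  expect_true(all(pe <= apply(members, 1, max) + 1e-12))
})

test_that("a single retained model is the ensemble; equal scores average", {
  tab <- toy_table(n_per_class = 25, seed = 83)
  m1 <- fit_sdm("GLM", tab, seed = 1)
  m2 <- fit_sdm("CTA", tab, seed = 1)
  q <- data.frame(x1 = seq(-3, 3, 0.5), x2 = 0)
  solo <- build_ensemble(list(GLM = m1), c(GLM = 0.7))
  expect_equal(predict(solo, q), predict(m1, q))
  pair <- build_ensemble(list(GLM = m1, CTA = m2), c(GLM = 0.8, CTA = 0.8))
  expect_equal(predict(pair, q), (predict(m1, q) + predict(m2, q)) / 2)
})

test_that("ensemble weights are invariant to common score rescaling; all-zero errors", {
  tab <- toy_table(n_per_class = 25, seed = 84)
  m <- list(GLM = fit_sdm("GLM", tab, seed = 1),
            CTA = fit_sdm("CTA", tab, seed = 1))
  w1 <- build_ensemble(m, c(GLM = 0.9, CTA = 0.3))$weights
  w2 <- build_ensemble(m, c(GLM = 0.09, CTA = 0.03))$weights
  expect_equal(w1, w2)
  expect_error(build_ensemble(m, c(GLM = 0, CTA = -0.1)), "<= 0")
})

test_that("permutation importance is zero for an ignored predictor", {
  # decoy is constant in training, so the learner cannot use it
  tab <- toy_table(n_per_class = 50, seed = 85)
  m <- fit_sdm("GLM", tab, seed = 1)
  d <- as.data.frame(tab)
  d$x2 <- rnorm(nrow(d))  # vary it at evaluation time
  # x2 is in the table but the toy signal is pure x1; a GLM gives it a tiny
  # coefficient. The stronger check: a predictor absent from the fitted
  # model (constant at training) has exactly zero importance.
  tab2 <- tab; tab2$x2 <- 5
  m2 <- fit_sdm("GLM", tab2, seed = 1)
  expect_false("x2" %in% m2$predictors)
  imp <- permutation_importance(m2, tab, predictors = "x2", n_perm = 5,
                                seed = 2)
  expect_equal(imp$importance, 0)
  expect_equal(imp$se, 0)
})

test_that("an identity model's sole predictor has importance near 1", {
  m <- identity_model("x1")
  set.seed(86)
  tab <- data.frame(x1 = runif(3000))
  imp <- permutation_importance(m, tab, predictors = "x1", n_perm = 10,
                                seed = 3)
  # correlation of a sequence with its shuffle is O(1/sqrt(n))
  expect_lt(abs(imp$importance - 1), 0.05)
  expect_gt(imp$se, 0)
})

test_that("a permuted-label decoy predictor earns near-zero importance after refit", {
  set.seed(87)
  n <- 2000
  x1 <- c(rnorm(n / 2, 1.5), rnorm(n / 2, -1.5))
  occ <- rep(c(1, 0), each = n / 2)
  decoy <- sample(occ)  # label-shaped but independent of the response
  tab <- structure(data.frame(lon = 0, lat = 0, x1 = x1,
                              decoy = decoy + rnorm(n, sd = 0.01),
                              occ = occ, weight = 1),
                   class = c("training_table", "data.frame"),
                   predictors = c("x1", "decoy"))
  m <- fit_sdm("GLM", tab, seed = 1)
  imp <- permutation_importance(m, tab, n_perm = 10, seed = 4)
  expect_lt(abs(imp$importance[imp$predictor == "decoy"]), 0.05)
  expect_gt(imp$importance[imp$predictor == "x1"], 0.5)
})

test_that("permutation importance is seed-reproducible", {
  tab <- toy_table(n_per_class = 40, seed = 88)
  m <- fit_sdm("CTA", tab, seed = 1)
  a <- permutation_importance(m, tab, n_perm = 5, seed = 9)
  b <- permutation_importance(m, tab, n_perm = 5, seed = 9)
  expect_identical(a, b)
})

test_that("response curves hold other predictors at their means", {
  tab <- toy_table(n_per_class = 40, seed = 89)
  m <- fit_sdm("GLM", tab, seed = 1)
  rc <- response_curve(m, tab, "x1", n_points = 50)
  expect_equal(nrow(rc), 50)
  expect_true(all(rc$suitability >= 0 & rc$suitability <= 1))
  expect_equal(range(rc$x), range(tab$x1))
  # curve value at the training mean equals a direct model call
  at_mean <- data.frame(x1 = mean(tab$x1), x2 = mean(tab$x2))
  rc2 <- response_curve(m, tab, "x1", n_points = 3)
  direct <- predict(m, at_mean)
  nearest <- which.min(abs(rc2$x - mean(tab$x1)))
  probe <- data.frame(x1 = rc2$x[nearest], x2 = mean(tab$x2))
  expect_equal(rc2$suitability[nearest], predict(m, probe), tolerance = 1e-12)
  # an ignored predictor yields a flat curve; identity model is monotone
  flat <- response_curve(constant_model(0.4, c("x1", "x2")), tab, "x2")
  expect_equal(diff(range(flat$suitability)), 0)
  mono <- response_curve(identity_model("x1", c("x1", "x2")),
                         data.frame(x1 = runif(100), x2 = runif(100)), "x1")
  expect_true(all(diff(mono$suitability) >= 0))
})
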