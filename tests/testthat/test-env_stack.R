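# Grid geometry, layer I/O, and the collinearity screen.

test_that("grid_spec dimensions follow the extent and cell size", {
  g <- grid_spec(50, 180, -50, 50, cell_size = 1 / 12)
  expect_equal(g$n_cols, round((180 - 50) * 12))
  expect_equal(g$n_rows, round(100 * 12))
  expect_error(grid_spec(10, 10, 0, 5), "lon_max")
  expect_error(grid_spec(0, 10, 0, 5, cell_size = -1))
  # longitudes in [180, 360) normalise to the western hemisphere
  g2 <- grid_spec(200, 220, 0, 10, cell_size = 1)
  expect_equal(g2$lon_min, -160)
})

test_that("cell indexing is half-open and round-trips through cell centers", {
  g <- grid_spec(0, 10, 0, 10, cell_size = 1)
  rc <- cell_index(g, c(0, 9.999, 10, 0.5), c(9.999, 0, 5, 0.5))
  expect_equal(rc$col, c(1L, 10L, NA, 1L))
  expect_equal(rc$row, c(1L, 10L, NA, 10L))
  ctr <- cell_center(g, 1:10, 1:10)
  rc2 <- cell_index(g, ctr$lon, ctr$lat)
  expect_equal(rc2$row, 1:10)
  expect_equal(rc2$col, 1:10)
})

test_that("ASCII grid round-trip preserves values, mask, and statistics", {
  g <- grid_spec(0, 3, 0, 3, cell_size = 1)
  vals <- matrix(c(1.5, 2, 3, NA, 5, 6, 7, 8, 9.25), 3, 3, byrow = TRUE)
  lyr <- env_layer("T", vals, g, units = "degC")
  written_mean <- mean(vals, na.rm = TRUE)  # oracle fixed before writing
  f <- withr::local_tempfile(fileext = ".asc")
  write_layer(lyr, f)
  back <- read_layer(f, name = "T")
  expect_equal(back$values, vals)
  expect_equal(sum(!is.na(back$values)), 8)
  expect_equal(mean(back$values, na.rm = TRUE), written_mean)
  expect_true(same_grid <- identical(back$grid$n_rows, g$n_rows))
  # second round trip is the identity
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_layer(back, f2)
  expect_equal(read_layer(f2)$values, back$values)
})

test_that("stack construction rejects grid mismatches and duplicate names", {
  g <- grid_spec(0, 4, 0, 4, cell_size = 1)
  g2 <- grid_spec(0, 5, 0, 5, cell_size = 1)
  a <- env_layer("A", matrix(1, 4, 4), g)
  b <- env_layer("B", matrix(2, 4, 4), g)
  bad <- env_layer("C", matrix(3, 5, 5), g2)
  expect_error(layer_stack(a, bad), "grid mismatch")
  expect_error(layer_stack(a, a), "duplicate")
  expect_equal(names(layer_stack(a, b)), c("A", "B"))
})

test_that("joint mask shrinks monotonically as layers are added", {
  g <- grid_spec(0, 10, 0, 10, cell_size = 1)
  set.seed(4)
  layers <- lapply(1:4, function(i) {
    v <- matrix(rnorm(100), 10, 10)
    v[sample.int(100, 10)] <- NA
    env_layer(paste0("L", i), v, g)
  })
  prev <- Inf
  for (i in 1:4) {
    m <- sum(joint_mask(layer_stack(layers[1:i])))
    expect_lte(m, prev)
    prev <- m
  }
})

test_that("pearson_matrix matches the textbook formula and flags constants", {
  g <- grid_spec(0, 100, -50, 50, cell_size = 1)
  set.seed(9)
  x <- matrix(rnorm(10000), 100, 100)
  y <- matrix(rnorm(10000), 100, 100)
  stk <- layer_stack(env_layer("X", x, g), env_layer("Y", y, g),
                     env_layer("negX", -x, g), env_layer("X2", x, g),
                     env_layer("K", matrix(1, 100, 100), g))
  cm <- pearson_matrix(stk)
  expect_true(isSymmetric(unname(cm)))
  expect_equal(unname(diag(cm)), rep(1, 5))
  expect_equal(cm["X", "X2"], 1)
  expect_equal(cm["X", "negX"], -1)
  # direct sum-formula oracle for the independent pair
  xv <- as.vector(x); yv <- as.vector(y); n <- length(xv)
  r_oracle <- (sum(xv * yv) - n * mean(xv) * mean(yv)) /
    sqrt((sum(xv^2) - n * mean(xv)^2) * (sum(yv^2) - n * mean(yv)^2))
  expect_equal(cm["X", "Y"], r_oracle, tolerance = 1e-12)
  expect_lt(abs(cm["X", "Y"]), 0.03)
  # constant layer: undefined, not zero
  expect_true(all(is.na(cm["K", c("X", "Y", "negX", "X2")])))
})

test_that("pearson_matrix is invariant to affine rescaling (sign-flips under negation)", {
  stk <- tiny_stack(seed = 3)
  cm <- pearson_matrix(stk)
  scaled <- stk
  scaled$layers$T$values <- 3.5 * scaled$layers$T$values - 100
  scaled$layers$Sal$values <- -2 * scaled$layers$Sal$values
  cm2 <- pearson_matrix(scaled)
  expect_equal(cm2["T", "Depth"], cm["T", "Depth"], tolerance = 1e-12)
  expect_equal(cm2["Sal", "Depth"], -cm["Sal", "Depth"], tolerance = 1e-12)
  expect_equal(abs(cm2["T", "Sal"]), abs(cm["T", "Sal"]), tolerance = 1e-12)
})

test_that("select_uncorrelated applies the greedy rule exactly", {
  # single layer retained trivially
  one <- matrix(1, 1, 1, dimnames = list("A", "A"))
  expect_equal(select_uncorrelated(one), "A")
  # high-correlation pair: priority wins
  two <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(select_uncorrelated(two), "A")
  expect_equal(select_uncorrelated(two, priority = c("B", "A")), "B")
  # 5-layer constructed matrix vs a brute-force oracle of the rule
  greedy_oracle <- function(corr, thr, priority) {
    kept <- character()
    for (nm in priority)
      if (all(abs(corr[nm, kept]) < thr)) kept <- c(kept, nm)
    kept
  }
  set.seed(21)
  for (rep in 1:20) {
    p <- 5
    L <- matrix(rnorm(p * p), p)
    cm <- stats::cov2cor(crossprod(L) + diag(p) * 0.1)
    dimnames(cm) <- list(LETTERS[1:p], LETTERS[1:p])
    pri <- sample(LETTERS[1:p])
    got <- select_uncorrelated(cm, threshold = 0.5, priority = pri)
    expect_equal(got, greedy_oracle(cm, 0.5, pri))
    # no retained pair violates the threshold
    if (length(got) > 1)
      expect_true(all(abs(cm[got, got][upper.tri(diag(length(got)))]) < 0.5))
  }
})
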