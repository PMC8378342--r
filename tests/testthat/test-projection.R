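# Projection, binarization, scenario shifts, range-change accounting.

test_that("projection reproduces direct model calls cell by cell", {
  stk <- tiny_stack(seed = 91)
  sp <- generate_virtual_species(stk, n_presences = 60, seed = 91)
  bg <- generate_pseudo_absences(stk, sp$presences, n = 300, seed = 91)
  tab <- suppressMessages(build_training_table(stk, sp$presences, bg))
  m <- fit_sdm("GLM", tab, seed = 1)
  map <- project_sdm(m, stk)
  expect_identical(is.na(map$values), !joint_mask(stk))
  v <- map$values[!is.na(map$values)]
  expect_true(all(v >= 0 & v <= 1))
  # values at presence points equal direct calls
  env <- extract_values(stk, sp$presences$lon, sp$presences$lat)
  rc <- cell_index(stk$grid, sp$presences$lon, sp$presences$lat)
  expect_equal(map$values[cbind(rc$row, rc$col)], predict(m, env),
               tolerance = 1e-12)
  # sampled-cell oracle: map mean equals mean of direct calls
  set.seed(92)
  cells <- which(!is.na(map$values))
  pick <- sample(cells, 500, replace = TRUE)
  ai <- arrayInd(pick, dim(map$values))
  ctr <- cell_center(stk$grid, ai[, 1], ai[, 2])
  direct <- predict(m, extract_values(stk, ctr$lon, ctr$lat))
  expect_equal(mean(map$values[pick]), mean(direct), tolerance = 1e-12)
  # a constant model projects a uniform map
  cmap <- project_sdm(constant_model(0.3, "T"), stk)
  expect_equal(unique(cmap$values[!is.na(cmap$values)]), 0.3)
  expect_error(project_sdm(constant_model(1, "NotALayer"), stk),
               "NotALayer")
})

test_that("binarize thresholds with >= and counts match a direct scan", {
  stk <- tiny_stack(seed = 93)
  map <- project_sdm(constant_model(0.5, "T"), stk)
  set.seed(93)
  map$values[!is.na(map$values)] <- runif(sum(!is.na(map$values)))
  all_in <- binarize(map, 0)
  expect_equal(sum(all_in$values, na.rm = TRUE), sum(!is.na(map$values)))
  top <- binarize(map, 1)
  expect_equal(sum(top$values, na.rm = TRUE),
               sum(map$values == 1, na.rm = TRUE))
  for (t in c(0.25, 0.5, 0.9)) {
    b <- binarize(map, t)
    expect_equal(sum(b$values, na.rm = TRUE),
                 sum(map$values >= t, na.rm = TRUE))
  }
  expect_error(binarize(map, 1.5))
})

test_that("range_change reproduces hand-built loss/gain configurations", {
  mk <- function(v) binary_map(matrix(v, 10, 10))
  a <- mk(rep(c(1, 0), 50))
  same <- range_change(a, a)
  expect_equal(same$PercLoss, 0)
  expect_equal(same$PercGain, 0)
  expect_equal(same$PercStable, 100)
  expect_equal(same$SpeciesRangeChange, 0)
  # future all-unsuitable: change -100
  gone <- range_change(a, mk(rep(0, 100)))
  expect_equal(gone$SpeciesRangeChange, -100)
  expect_equal(gone$PercLoss, 100)
  expect_error(range_change(mk(rep(0, 100)), a), "no currently suitable")
})

test_that("range_change statistics match an exhaustive cell tally on random maps", {
  for (seed in 1:10) {
    pr <- random_binary_pair(20, 20, seed = seed)
    rc <- range_change(pr$current, pr$future)
    cv <- pr$current$values; fv <- pr$future$values
    lost <- gained <- stable <- cur <- 0
    for (i in 1:20) for (j in 1:20) {
      if (is.na(cv[i, j])) next
      if (cv[i, j] == 1) cur <- cur + 1
      if (cv[i, j] == 1 && fv[i, j] == 0) lost <- lost + 1
      if (cv[i, j] == 0 && fv[i, j] == 1) gained <- gained + 1
      if (cv[i, j] == 1 && fv[i, j] == 1) stable <- stable + 1
    }
    expect_equal(rc$PercLoss, 100 * lost / cur)
    expect_equal(rc$PercGain, 100 * gained / cur)
    expect_equal(rc$PercStable, 100 * stable / cur)
    expect_equal(rc$SpeciesRangeChange, 100 * (gained - lost) / cur)
  }
})

test_that("mismatched grids or masks are rejected", {
  a <- binary_map(matrix(1, 5, 5))
  b <- binary_map(matrix(1, 6, 6))
  expect_error(range_change(a, b), "different grids")
  c <- binary_map(matrix(1, 5, 5))
  c$values[1, 1] <- NA
  expect_error(range_change(a, c), "different masks")
})

test_that("apply_scenario shifts dynamic layers and preserves static ones", {
  stk <- tiny_stack(seed = 94)
  zero <- scenario_delta("null_shift")
  s0 <- apply_scenario(stk, zero)
  expect_equal(s0$layers$T$values, stk$layers$T$values)
  expect_equal(s0$scenario_label, "null_shift")
  # uniform +2.87 degC: future-minus-current mean difference is exactly 2.87
  warm <- apply_scenario(stk, scenario_delta("warm", T = 2.87, Sal = -0.26))
  dT <- warm$layers$T$values - stk$layers$T$values
  expect_equal(mean(dT, na.rm = TRUE), 2.87)
  expect_equal(unique(round(dT[!is.na(dT)], 12)), 2.87)
  expect_equal(warm$layers$Sal$values, stk$layers$Sal$values - 0.26)
  expect_equal(warm$layers$Depth$values, stk$layers$Depth$values)
  expect_equal(warm$layers$Dshore$values, stk$layers$Dshore$values)
  # spatially varying delta: per-cell difference equals the field exactly
  fld <- matrix(seq_len(length(stk$layers$T$values)) / 1000,
                nrow(stk$layers$T$values))
  sv <- apply_scenario(stk, scenario_delta("sv", T = fld))
  diffs <- sv$layers$T$values - stk$layers$T$values
  sea <- !is.na(stk$layers$T$values)
  expect_equal(diffs[sea], fld[sea])
  expect_error(apply_scenario(stk, scenario_delta("bad", Chla = 1)),
               "missing layer")
  expect_error(scenario_delta("static", Depth = 5), "static")
})

test_that("area weighting reduces to cell counting on an equator-symmetric grid", {
  pr <- random_binary_pair(20, 20, p_valid = 1, seed = 7)
  # unit-degree default grid is not symmetric about the equator; rebuild it
  g <- grid_spec(0, 20, -10, 10, cell_size = 1)
  cur <- binary_map(pr$current$values, grid = g)
  fut <- binary_map(pr$future$values, grid = g)
  plain <- range_change(cur, fut)
  weighted <- range_change(cur, fut, area_weighted = TRUE)
  # identities hold under both accountings
  for (rc in list(plain, weighted)) {
    expect_equal(rc$PercLoss + rc$PercStable, 100)
    expect_equal(rc$SpeciesRangeChange, rc$PercGain - rc$PercLoss)
  }
  # weights differ so percentages generally differ
  expect_false(isTRUE(all.equal(plain$counts[["current_suitable"]],
                                weighted$counts[["current_suitable"]])))
})
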