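# The top-level fitted-model object and the pipeline commands.

small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      stk <- tiny_stack(seed = 111, n = 40)
      sp <- generate_virtual_species(stk, n_presences = 80, seed = 111)
      cache <<- list(
        stack = stk, species = sp,
        fit = suppressWarnings(
          esdm(sp$presences, stk,
               algorithms = c("GLM", "CTA", "SRE", "MARS"),
               n_pseudo = 500, k = 5, repetitions = 2, seed = 112)))
    }
    cache
  }
})

test_that("esdm runs the full workflow and returns a coherent fit", {
  x <- small_fit()
  fit <- x$fit
  expect_s3_class(fit, "esdm")
  expect_equal(nrow(fit$records), 4 * 5 * 2)  # algorithms x folds x reps
  expect_true(all(fit$retained %in% c("GLM", "CTA", "SRE", "MARS")))
  expect_gte(length(fit$retained), 1)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  expect_true(fit$threshold >= 0 && fit$threshold <= 1)
  # printed summary carries the per-algorithm means
  s <- summary(fit)
  expect_setequal(s$means$algorithm, c("GLM", "CTA", "SRE", "MARS"))
  expect_output(print(s), "cross-validation means")
  expect_output(print(fit), "retained")
})

test_that("esdm reruns are reproducible from the master seed", {
  x <- small_fit()
  fit2 <- suppressWarnings(
    esdm(x$species$presences, x$stack,
         algorithms = c("GLM", "CTA", "SRE", "MARS"),
         n_pseudo = 500, k = 5, repetitions = 2, seed = 112))
  expect_identical(x$fit$records, fit2$records)
  expect_identical(x$fit$threshold, fit2$threshold)
  expect_identical(x$fit$current$values, fit2$current$values)
})

test_that("predict.esdm serves data frames and stacks, continuous and binary", {
  x <- small_fit()
  fit <- x$fit
  tab <- as.data.frame(fit$table)[1:20, ]
  p <- predict(fit, tab)
  expect_length(p, 20)
  expect_true(all(p >= 0 & p <= 1))
  pb <- predict(fit, tab, type = "binary")
  expect_equal(pb, as.numeric(p >= fit$threshold))
  map <- predict(fit, x$stack)
  expect_s3_class(map, "suitability_map")
  bmap <- predict(fit, x$stack, type = "binary")
  expect_s3_class(bmap, "binary_map")
  expect_equal(bmap$threshold, fit$threshold)
})

test_that("variable importance and response curves work off the fit", {
  x <- small_fit()
  imp <- variable_importance(x$fit, n_perm = 3, seed = 5)
  expect_setequal(imp$predictor, attr(x$fit$table, "predictors"))
  rc <- response_curve(x$fit$ensemble, x$fit$table, "Depth", n_points = 20)
  expect_equal(nrow(rc), 20)
})

test_that("range_change_table carries the scenario columns and identities", {
  x <- small_fit()
  tab <- range_change_table(x$fit$ensemble, x$stack,
                            scenarios = default_scenarios(),
                            threshold = x$fit$threshold)
  expect_equal(dim(tab), c(4, 8))
  expect_equal(rownames(tab), c("PercLoss", "PercGain", "PercStable",
                                "SpeciesRangeChange"))
  for (j in seq_len(ncol(tab))) {
    expect_equal(tab["PercLoss", j] + tab["PercStable", j], 100)
    expect_equal(tab["SpeciesRangeChange", j],
                 tab["PercGain", j] - tab["PercLoss", j])
  }
})

test_that("run configs validate and fill the standard defaults", {
  cfg <- read_run_config()
  expect_equal(cfg$pseudo_absences$n, 5000)
  expect_equal(cfg$cv$k, 5)
  expect_equal(cfg$cv$repetitions, 10)
  expect_equal(cfg$gates$tss_min, 0.80)
  expect_equal(cfg$gates$auc_min, 0.85)
  expect_equal(cfg$extent$lon_min, 50)
  expect_equal(cfg$extent$lat_max, 50)
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines("cv:\n  k: 3\nseed: 9", f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$cv$k, 3)
  expect_equal(cfg2$cv$repetitions, 10)  # unset fields keep defaults
  expect_equal(cfg2$seed, 9)
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("algorithms: [GLM, NOTANALG]", bad)
  expect_error(read_run_config(bad), "NOTANALG")
  expect_error(read_run_config("/nonexistent.yml"), "not found")
})

test_that("the pipeline commands chain on disk from one config", {
  out <- withr::local_tempdir()
  cfg <- read_run_config(overrides = list(
    out_dir = out, seed = 21,
    extent = list(lon_min = 100, lon_max = 140, lat_min = -20, lat_max = 20),
    cell_size = 1, n_presences = 82,
    pseudo_absences = list(n = 400, strategy = "sre", quantile = 0.025),
    cv = list(k = 5, repetitions = 1),
    algorithms = c("GLM", "CTA", "SRE")))
  suppressMessages(cmd_simulate(cfg))
  expect_true(file.exists(file.path(out, "presences.csv")))
  expect_true(file.exists(file.path(out, "stack", "manifest.yml")))
  expect_equal(nrow(read.csv(file.path(out, "presences.csv"))), 82)
  stack_back <- read_stack(file.path(out, "stack", "manifest.yml"))
  expect_setequal(names(stack_back), c("T", "Sal", "CV", "Ice", "Depth",
                                       "Dshore"))
  # same seed -> identical files
  out2 <- withr::local_tempdir()
  suppressMessages(cmd_simulate(read_run_config(overrides =
    utils::modifyList(unclass(cfg), list(out_dir = out2)))))
  expect_identical(readLines(file.path(out, "presences.csv")),
                   readLines(file.path(out2, "presences.csv")))
  expect_identical(readLines(file.path(out, "stack", "T.asc")),
                   readLines(file.path(out2, "stack", "T.asc")))

  fit <- suppressMessages(suppressWarnings(cmd_fit_evaluate(cfg)))
  ev <- read.csv(file.path(out, "evaluation.csv"))
  expect_equal(nrow(ev), 3 * 5 * 1)  # algorithms x folds x repetitions
  expect_true(file.exists(file.path(out, "gate_report.json")))
  expect_true(file.exists(file.path(out, "importance.csv")))

  tab <- suppressMessages(cmd_project(cfg, fit = fit))
  expect_equal(dim(tab), c(4, 8))
  rc_csv <- read.csv(file.path(out, "range_change.csv"), check.names = FALSE)
  expect_equal(ncol(rc_csv), 9)  # statistic column + 8 scenarios
  for (j in 2:9) {
    expect_equal(rc_csv[1, j] + rc_csv[3, j], 100, tolerance = 1e-9)
    expect_equal(rc_csv[4, j], rc_csv[2, j] - rc_csv[1, j], tolerance = 1e-9)
  }
  expect_true(file.exists(file.path(out, "maps", "binary_RCP85_2100s.asc")))
})

test_that("the command-line wrapper exits nonzero on a malformed config", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "esdm-pipeline.R", package = "esdm")
  expect_true(nzchar(cli))
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("cell_size: -1", bad)
  st <- system2("Rscript", c(cli, "simulate", "--config", shQuote(bad)),
                stdout = FALSE, stderr = FALSE)
  expect_gt(st, 0)
  st2 <- system2("Rscript", c(cli, "badcommand"), stdout = FALSE,
                 stderr = FALSE)
  expect_gt(st2, 0)
})
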