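# Run configuration and the three pipeline commands (simulate, fit/evaluate,
# project) that tie the stages together on disk. A thin command-line wrapper
# lives in inst/cli/esdm-pipeline.R.

default_config <- function() {
  list(
    out_dir = "esdm_run",
    presences = NULL,            # CSV; NULL = use the simulated species
    stack_manifest = NULL,       # YAML; NULL = use the simulated stack
    extent = list(lon_min = 50, lon_max = 180, lat_min = -50, lat_max = 50),
    cell_size = 1,               # degrees; simulation resolution
    thin = TRUE,
    n_presences = 82,            # simulated species target
    pseudo_absences = list(n = 5000, strategy = "sre", quantile = 0.025),
    cv = list(k = 5, repetitions = 10),
    gates = list(tss_min = 0.80, auc_min = 0.85),
    ensemble_metric = "TSS",
    algorithms = sdm_algorithms(),
    scenarios = "default",       # the eight RCP x horizon deltas
    seed = 1L)
}

#' Load a run configuration
#'
#' Reads a YAML configuration and fills unset fields with the package
#' defaults, which equal the standard workflow settings (5000
#' pseudo-absences in contrasting conditions, fivefold CV with 10
#' repetitions, gates TSS > 0.80 and AUC > 0.85, TSS-weighted ensemble, the
#' eight RCP scenarios). Numeric fields are validated on load.
#'
#' @param path YAML file; `NULL` gives the pure defaults.
#' @param overrides named list applied on top (e.g. `list(seed = 42)`).
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  with(cfg, {
    stopifnot(cell_size > 0, n_presences >= 1,
              pseudo_absences$n >= 1, cv$k >= 2, cv$repetitions >= 1,
              gates$tss_min >= -1, gates$tss_min <= 1,
              gates$auc_min >= 0, gates$auc_min <= 1)
  })
  if (!all(cfg$algorithms %in% sdm_algorithms()))
    stop("unknown algorithm(s): ",
         paste(setdiff(cfg$algorithms, sdm_algorithms()), collapse = ", "))
  structure(cfg, class = "run_config")
}

config_grid <- function(config) {
  grid_spec(config$extent$lon_min, config$extent$lon_max,
            config$extent$lat_min, config$extent$lat_max,
            cell_size = config$cell_size)
}

config_scenarios <- function(config) {
  if (identical(config$scenarios, "default")) return(default_scenarios())
  lapply(config$scenarios, function(s)
    do.call(scenario_delta, c(list(id = s$id), s$deltas)))
}

#' Simulate a study system to disk
#'
#' Generates the synthetic environmental stack and virtual species for the
#' configured extent and writes them in the same formats the real pipeline
#' reads: ASCII grid layers + manifest, a presences CSV, the truth
#' suitability and truth binary maps, and a JSON run manifest.
#'
#' @param config a [read_run_config()] result.
#' @return the output directory, invisibly; see the `manifest.json` inside.
#' @export
cmd_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config_grid(config)
  stack <- generate_env_stack(grid, seed = config$seed)
  sp <- generate_virtual_species(stack, n_presences = config$n_presences,
                                 seed = config$seed + 1L)
  stack_dir <- file.path(config$out_dir, "stack")
  manifest <- write_stack(stack, stack_dir)
  utils::write.csv(as.data.frame(sp$presences),
                   file.path(config$out_dir, "presences.csv"),
                   row.names = FALSE)
  write_layer(structure(list(name = "truth", units = "", grid = grid,
                             values = sp$truth$suitability$values),
                        class = "env_layer"),
              file.path(config$out_dir, "truth_suitability.asc"))
  write_layer(structure(list(name = "truth_bin", units = "", grid = grid,
                             values = sp$truth$binary$values),
                        class = "env_layer"),
              file.path(config$out_dir, "truth_binary.asc"))
  info <- list(stage = "simulate", seed = config$seed,
               n_presences = nrow(sp$presences),
               n_sea_cells = sum(joint_mask(stack)),
               layers = names(stack), stack_manifest = manifest)
  jsonlite::write_json(info, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("cmd_simulate: %d layers, %d presences -> %s",
                  length(names(stack)), nrow(sp$presences), config$out_dir))
  invisible(config$out_dir)
}

load_inputs <- function(config) {
  if (is.null(config$stack_manifest)) {
    m <- file.path(config$out_dir, "stack", "manifest.yml")
    if (!file.exists(m))
      stop("no stack manifest; run cmd_simulate() or set stack_manifest")
    config$stack_manifest <- m
  }
  if (is.null(config$presences)) {
    p <- file.path(config$out_dir, "presences.csv")
    if (!file.exists(p))
      stop("no presence file; run cmd_simulate() or set presences")
    config$presences <- p
  }
  list(stack = read_stack(config$stack_manifest),
       presences = read_presences(config$presences))
}

#' Fit and evaluate the ensemble from configured inputs
#'
#' Loads the presences and stack, runs [esdm()] with the configured design,
#' and writes the per-fold evaluation CSV (algorithm, repetition, fold, TSS,
#' AUC, threshold — 500 rows for the full 10-algorithm design), the gate
#' report, the importance table, the per-predictor response curves, and the
#' fitted model bundle (`esdm_fit.rds`) for [cmd_project()].
#'
#' @param config a [read_run_config()] result.
#' @return the fitted [esdm()] object, invisibly.
#' @export
cmd_fit_evaluate <- function(config) {
  inp <- load_inputs(config)
  fit <- esdm(inp$presences, inp$stack,
              algorithms = config$algorithms,
              n_pseudo = config$pseudo_absences$n,
              pa_strategy = config$pseudo_absences$strategy,
              envelope_quantile = config$pseudo_absences$quantile,
              k = config$cv$k, repetitions = config$cv$repetitions,
              tss_min = config$gates$tss_min, auc_min = config$gates$auc_min,
              weighting_metric = config$ensemble_metric,
              thin = config$thin, seed = config$seed)
  utils::write.csv(fit$records,
                   file.path(config$out_dir, "evaluation.csv"),
                   row.names = FALSE)
  imp <- variable_importance(fit, seed = config$seed)
  utils::write.csv(imp, file.path(config$out_dir, "importance.csv"),
                   row.names = FALSE)
  curves <- do.call(rbind, lapply(attr(fit$table, "predictors"), function(p)
    response_curve(fit$ensemble, fit$table, p)))
  utils::write.csv(curves, file.path(config$out_dir, "response_curves.csv"),
                   row.names = FALSE)
  gate <- list(stage = "fit_evaluate", retained = fit$retained,
               means = fit$means, threshold = fit$threshold,
               weights = as.list(coef(fit)))
  jsonlite::write_json(gate, file.path(config$out_dir, "gate_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(fit, file.path(config$out_dir, "esdm_fit.rds"))
  message(sprintf("cmd_fit_evaluate: %d evaluation rows; retained %s",
                  nrow(fit$records), paste(fit$retained, collapse = ", ")))
  invisible(fit)
}

#' Project the fitted ensemble under all scenarios
#'
#' Loads the fitted bundle, projects the current and every configured
#' scenario stack, binarizes at the frozen training threshold, writes the
#' suitability and binary maps (`.asc`), and assembles the range-change
#' table (4 statistics x scenarios) as CSV.
#'
#' @param config a [read_run_config()] result.
#' @param fit optionally, an [esdm()] object (skips reading the bundle).
#' @return the range-change table, invisibly.
#' @export
cmd_project <- function(config, fit = NULL) {
  if (is.null(fit)) {
    f <- file.path(config$out_dir, "esdm_fit.rds")
    if (!file.exists(f)) stop("no fitted bundle; run cmd_fit_evaluate() first")
    fit <- readRDS(f)
  }
  scen <- config_scenarios(config)
  map_dir <- file.path(config$out_dir, "maps")
  dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
  save_map <- function(map, nm) {
    write_layer(structure(list(name = nm, units = "", grid = map$grid,
                               values = map$values), class = "env_layer"),
                file.path(map_dir, paste0(nm, ".asc")))
  }
  save_map(fit$current, "suitability_current")
  save_map(binarize(fit$current, fit$threshold), "binary_current")
  for (sc in scen) {
    m <- project_sdm(fit$ensemble, apply_scenario(fit$stack, sc))
    save_map(m, paste0("suitability_", sc$id))
    save_map(binarize(m, fit$threshold), paste0("binary_", sc$id))
  }
  tab <- range_change_table(fit$ensemble, fit$stack, scenarios = scen,
                            threshold = fit$threshold)
  utils::write.csv(cbind(statistic = rownames(tab), tab),
                   file.path(config$out_dir, "range_change.csv"),
                   row.names = FALSE)
  message(sprintf("cmd_project: %d scenarios -> %s", length(scen),
                  file.path(config$out_dir, "range_change.csv")))
  invisible(tab)
}
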