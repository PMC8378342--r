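# Projection onto layer stacks, binarization, scenario shifts, and
# range-change accounting.

#' Project a model onto an environmental stack
#'
#' Predicts suitability for every jointly valid cell; masked cells stay
#' masked.
#'
#' @param model an `sdm_model` or `sdm_ensemble`.
#' @param stack a [layer_stack()] supplying every predictor the model uses.
#' @return a `suitability_map`: an [env_layer()]-like object with values in
#'   `[0, 1]` and the stack's `scenario_label`.
#' @export
project_sdm <- function(model, stack) {
  need <- model_predictors(model)
  missing <- setdiff(need, names(stack))
  if (length(missing))
    stop("stack lacks predictor layer(s): ", paste(missing, collapse = ", "))
  mask <- joint_mask(stack)
  tab <- stack_table(stack, mask)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[attr(tab, "cell")] <- predict(model, tab)
  structure(list(grid = stack$grid, values = vals,
                 scenario_label = stack$scenario_label),
            class = c("suitability_map"))
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("suitability_map '%s': %d valid cells, mean %.3f\n",
              x$scenario_label, length(v), mean(v)))
  invisible(x)
}

#' Convert a suitability map to a binary map
#'
#' A valid cell is suitable iff its suitability is `>= threshold`. The
#' natural choice of threshold is the ensemble's TSS-maximising threshold on
#' the training data, frozen from the current period and reused for every
#' future scenario.
#'
#' @param map a [project_sdm()] result.
#' @param threshold cutoff in `[0, 1]`.
#' @return a `binary_map` with 0/1 values on valid cells and the threshold
#'   stored.
#' @export
binarize <- function(map, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  vals <- ifelse(is.na(map$values), NA_real_,
                 as.numeric(map$values >= threshold))
  structure(list(grid = map$grid, values = vals, threshold = threshold,
                 scenario_label = map$scenario_label),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("binary_map '%s' (t = %.4g): %d suitable / %d valid cells\n",
              x$scenario_label, x$threshold, sum(v), length(v)))
  invisible(x)
}

#' Construct a binary map directly from 0/1 values
#'
#' Convenience constructor for range-change arithmetic on externally defined
#' suitable/unsuitable patterns.
#'
#' @param values 0/1 matrix (NA = masked).
#' @param grid a [grid_spec()]; defaults to a unit-degree grid of matching
#'   shape.
#' @param threshold threshold to record.
#' @param scenario_label label.
#' @return a `binary_map`.
#' @export
binary_map <- function(values, grid = NULL, threshold = 0.5,
                       scenario_label = "") {
  stopifnot(is.matrix(values))
  if (!all(values %in% c(0, 1) | is.na(values)))
    stop("values must be 0/1 or NA")
  if (is.null(grid)) {
    # synthesise a geographically valid grid of matching shape
    cs <- min(1, 85 / nrow(values), 170 / ncol(values))
    grid <- grid_spec(0, ncol(values) * cs, 0, nrow(values) * cs,
                      cell_size = cs)
  }
  structure(list(grid = grid, values = values, threshold = threshold,
                 scenario_label = scenario_label),
            class = "binary_map")
}

#' Range change between two binary maps
#'
#' Tallies cells lost (suitable now, unsuitable in the future), gained
#' (unsuitable now, suitable in the future) and stable (suitable in both),
#' all as percentages of the *current* suitable area:
#' `PercLoss = 100 * lost / currentSuitable`, likewise `PercGain` and
#' `PercStable`, and `SpeciesRangeChange = PercGain - PercLoss` — i.e. 100 x
#' (future suitable - current suitable) / current suitable. By construction
#' `PercLoss + PercStable = 100`.
#'
#' @param current,future `binary_map`s on identical grids and masks.
#' @param area_weighted if `TRUE`, cells are weighted by `cos(latitude)`
#'   (approximate geodesic area) instead of counted; default `FALSE`.
#' @return an object of class `range_change` with the four percentages and
#'   the underlying counts.
#' @export
range_change <- function(current, future, area_weighted = FALSE) {
  if (!same_grid(current$grid, future$grid))
    stop("current and future maps are on different grids")
  cv <- current$values; fv <- future$values
  if (!identical(is.na(cv), is.na(fv)))
    stop("current and future maps have different masks")
  ok <- !is.na(cv)
  w <- if (area_weighted) {
    lat <- cell_center(current$grid, row(cv), col(cv))$lat
    cos(lat * pi / 180)
  } else matrix(1, nrow(cv), ncol(cv))
  cur <- sum(w[ok & cv == 1])
  if (cur <= 0) stop("no currently suitable cells")
  lost <- sum(w[ok & cv == 1 & fv == 0])
  gained <- sum(w[ok & cv == 0 & fv == 1])
  stable <- sum(w[ok & cv == 1 & fv == 1])
  structure(list(
    counts = c(current_suitable = cur, lost = lost, gained = gained,
               stable = stable),
    PercLoss = 100 * lost / cur,
    PercGain = 100 * gained / cur,
    PercStable = 100 * stable / cur,
    SpeciesRangeChange = 100 * (gained - lost) / cur,
    scenario = future$scenario_label),
    class = "range_change")
}

#' @export
print.range_change <- function(x, ...) {
  cat(sprintf("range_change%s:\n",
              if (nzchar(x$scenario)) paste0(" [", x$scenario, "]") else ""))
  cat(sprintf("  PercLoss %.3f  PercGain %.3f  PercStable %.3f  SpeciesRangeChange %.3f\n",
              x$PercLoss, x$PercGain, x$PercStable, x$SpeciesRangeChange))
  invisible(x)
}

#' Define a climate-scenario shift
#'
#' Additive per-predictor deltas applied to the dynamic layers; static
#' layers (ocean depth, distance to shore) are assumed constant in the
#' future and must not receive a delta.
#'
#' @param id scenario identifier, e.g. `"RCP85_2100s"`.
#' @param ... named deltas (scalar, or a matrix matching the grid), e.g.
#'   `T = 2.87, Sal = -0.26`.
#' @param static layer names that must stay constant; defaults to
#'   `c("Depth", "Dshore")`.
#' @return an object of class `scenario_delta`.
#' @export
scenario_delta <- function(id, ..., static = c("Depth", "Dshore")) {
  deltas <- list(...)
  if (length(deltas) && is.null(names(deltas)))
    stop("deltas must be named by layer")
  bad <- intersect(names(deltas), static)
  if (length(bad))
    stop("static layer(s) cannot be shifted: ", paste(bad, collapse = ", "))
  structure(list(id = id, deltas = deltas, static = static),
            class = "scenario_delta")
}

#' @export
print.scenario_delta <- function(x, ...) {
  d <- vapply(x$deltas, function(v) if (is.matrix(v)) NA_real_ else v, 0)
  cat(sprintf("scenario_delta '%s': %s\n", x$id,
              paste(sprintf("%s%+g", names(d), d), collapse = ", ")))
  invisible(x)
}

#' Apply a scenario shift to a stack
#'
#' Each layer named in the delta is shifted additively (uniformly, or
#' cellwise when the delta is a matrix); all other layers — including the
#' static depth and distance-to-shore layers — are copied unchanged. The
#' stack's scenario label becomes the delta's id.
#'
#' @param stack a [layer_stack()].
#' @param delta a [scenario_delta()].
#' @return the shifted [layer_stack()].
#' @export
apply_scenario <- function(stack, delta) {
  missing <- setdiff(names(delta$deltas), names(stack))
  if (length(missing))
    stop("delta refers to missing layer(s): ", paste(missing, collapse = ", "))
  layers <- lapply(stack$layers, function(l) {
    d <- delta$deltas[[l$name]]
    if (!is.null(d)) l$values <- l$values + d
    l
  })
  layer_stack(layers, scenario_label = delta$id)
}

#' Range-change table across scenarios
#'
#' Projects the model onto the current stack and onto each shifted scenario
#' stack, binarizes everything at one frozen threshold, and assembles the
#' classic 4-statistic x n-scenario table (PercLoss, PercGain, PercStable,
#' SpeciesRangeChange).
#'
#' @param model an `sdm_model` or `sdm_ensemble`.
#' @param stack the current-period [layer_stack()].
#' @param scenarios list of [scenario_delta()]s; default
#'   [default_scenarios()].
#' @param threshold binarization threshold (frozen across scenarios).
#' @return data.frame with rows PercLoss/PercGain/PercStable/
#'   SpeciesRangeChange and one column per scenario.
#' @export
range_change_table <- function(model, stack, scenarios = default_scenarios(),
                               threshold) {
  cur_bin <- binarize(project_sdm(model, stack), threshold)
  cols <- lapply(scenarios, function(sc) {
    fut <- binarize(project_sdm(model, apply_scenario(stack, sc)), threshold)
    rc <- range_change(cur_bin, fut)
    c(PercLoss = rc$PercLoss, PercGain = rc$PercGain,
      PercStable = rc$PercStable, SpeciesRangeChange = rc$SpeciesRangeChange)
  })
  out <- as.data.frame(cols)
  names(out) <- vapply(scenarios, `[[`, "", "id")
  out
}
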