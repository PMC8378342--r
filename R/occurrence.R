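# Presence records: ingestion, extent filtering, grid thinning,
# pseudo-absence generation.

#' Build a presence set from coordinates
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @param source_id optional record identifiers.
#' @return a `presence_set`: a data.frame with columns `lon`, `lat` and
#'   optionally `source_id`.
#' @export
presence_set <- function(lon, lat, source_id = NULL) {
  stopifnot(length(lon) == length(lat))
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("coordinates must be finite")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  df <- data.frame(lon = normalize_lon(lon), lat = lat)
  if (!is.null(source_id)) df$source_id <- as.character(source_id)
  structure(df, class = c("presence_set", "data.frame"))
}

#' Read presence records from CSV
#'
#' The file must have a header with columns `lon` and `lat` (a `source_id`
#' column is carried along if present).
#'
#' @param path CSV path.
#' @return a [presence_set()].
#' @export
read_presences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("presence CSV must have 'lon' and 'lat' columns: ", path)
  presence_set(df$lon, df$lat,
               source_id = if ("source_id" %in% names(df)) df$source_id)
}

#' @export
print.presence_set <- function(x, ...) {
  cat(sprintf("presence_set: %d records, lon [%.3f, %.3f], lat [%.3f, %.3f]\n",
              nrow(x), min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

#' Restrict presences to a grid's extent
#'
#' The extent is half-open: a point exactly on the upper longitude or
#' latitude bound is dropped. Filtering is idempotent. An empty result is a
#' warning, not an error.
#'
#' @param presences a [presence_set()].
#' @param grid a [grid_spec()] defining the extent.
#' @return the filtered [presence_set()]; retained/input counts are reported
#'   via `message()`.
#' @export
filter_extent <- function(presences, grid) {
  keep <- presences$lon >= grid$lon_min & presences$lon < grid$lon_max &
    presences$lat >= grid$lat_min & presences$lat < grid$lat_max
  out <- presences[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("filter_extent: retained %d of %d records", nrow(out),
                  nrow(presences)))
  if (!nrow(out)) warning("no presence records inside the extent")
  structure(out, class = c("presence_set", "data.frame"))
}

#' Thin presences to one record per grid cell
#'
#' Keeps the first record (in input order) falling in each occupied cell, so
#' densely sampled areas do not over-represent their environments. Records
#' outside the grid are dropped.
#'
#' @param presences a [presence_set()].
#' @param grid a [grid_spec()].
#' @return thinned [presence_set()]; one record per occupied cell.
#' @export
thin_to_grid <- function(presences, grid) {
  rc <- cell_index(grid, presences$lon, presences$lat)
  inside <- !is.na(rc$row)
  key <- paste(rc$row, rc$col)
  keep <- inside & !duplicated(key)
  out <- presences[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("thin_to_grid: %d records -> %d occupied cells",
                  nrow(presences), nrow(out)))
  structure(out, class = c("presence_set", "data.frame"))
}

#' Generate pseudo-absence points
#'
#' Samples background points, treated as absences, from the valid sea cells
#' of the stack. The default `"sre"` strategy draws only from cells whose
#' environmental vector falls *outside* the surface range envelope of the
#' presence data (quantile bounds per predictor), i.e. in contrasting
#' environmental conditions; `"random"` draws from all valid cells. Cells
#' already occupied by a presence are never used, and points are placed at
#' cell centres. If fewer eligible cells than `n` exist, sampling is with
#' replacement and a warning is issued.
#'
#' @param stack a [layer_stack()].
#' @param presences a [presence_set()] (non-empty).
#' @param n number of pseudo-absences; default 5000.
#' @param strategy `"sre"` (envelope exclusion, default) or `"random"`.
#' @param envelope_quantile per-margin quantile of the presence envelope;
#'   default 0.025 (bounds at the 2.5/97.5 percentiles).
#' @param seed RNG seed; the same seed reproduces the same points exactly.
#' @return a `background_set`: data.frame with columns `lon`, `lat` and the
#'   attribute `eligible_cells` (number of cells the draw came from).
#' @export
generate_pseudo_absences <- function(stack, presences, n = 5000,
                                     strategy = c("sre", "random"),
                                     envelope_quantile = 0.025, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(n >= 1, nrow(presences) >= 1)
  mask <- joint_mask(stack)
  rc <- cell_index(stack$grid, presences$lon, presences$lat)
  ok <- !is.na(rc$row)
  pres_cells <- unique((rc$col[ok] - 1L) * stack$grid$n_rows + rc$row[ok])

  tab <- stack_table(stack, mask)
  cells <- attr(tab, "cell")
  free <- !(cells %in% pres_cells)

  if (strategy == "sre") {
    penv <- extract_values(stack, presences$lon, presences$lat)
    penv <- penv[stats::complete.cases(penv), , drop = FALSE]
    if (nrow(penv) < 2L)
      stop("need at least two presences on valid cells to fit the envelope")
    env <- sre_fit(penv, quantile = envelope_quantile)
    inside <- sre_predict(env, tab) == 1
    eligible <- which(free & !inside)
    if (!length(eligible))
      stop("no valid cells outside the presence envelope; ",
           "use strategy = 'random'")
  } else {
    eligible <- which(free)
    if (!length(eligible)) stop("no valid cells available for background points")
  }

  set.seed(seed)
  if (length(eligible) < n) {
    warning(sprintf("only %d eligible cells for %d pseudo-absences; %s",
                    length(eligible), n, "sampling with replacement"))
    pick <- sample(eligible, n, replace = TRUE)
  } else {
    pick <- sample(eligible, n)
  }
  ctr <- cell_center(stack$grid, attr(tab, "row")[pick], attr(tab, "col")[pick])
  out <- data.frame(lon = ctr$lon, lat = ctr$lat)
  attr(out, "eligible_cells") <- length(eligible)
  attr(out, "strategy") <- strategy
  structure(out, class = c("background_set", "data.frame"))
}

#' Assemble the model training table
#'
#' Extracts predictor values at presence and background locations and builds
#' the fitting table with a binary response (`occ`: 1 presence, 0
#' pseudo-absence) and class-balanced case weights (each class carries half
#' the total weight, so 82 presences are not swamped by 5000
#' pseudo-absences; weights average 1).
#'
#' @param stack a [layer_stack()].
#' @param presences a [presence_set()].
#' @param background a background set from [generate_pseudo_absences()].
#' @return a `training_table`: data.frame with `lon`, `lat`, one column per
#'   predictor, `occ`, and `weight`; the predictor names are stored in the
#'   `"predictors"` attribute. Rows whose cell is masked are dropped.
#' @export
build_training_table <- function(stack, presences, background) {
  pts <- rbind(data.frame(lon = presences$lon, lat = presences$lat, occ = 1),
               data.frame(lon = background$lon, lat = background$lat, occ = 0))
  env <- extract_values(stack, pts$lon, pts$lat)
  keep <- stats::complete.cases(env)
  if (!all(keep))
    message(sprintf("build_training_table: dropped %d points on masked cells",
                    sum(!keep)))
  df <- cbind(pts[keep, , drop = FALSE], env[keep, , drop = FALSE])
  n1 <- sum(df$occ == 1); n0 <- sum(df$occ == 0)
  if (n1 == 0 || n0 == 0) stop("training table needs both classes")
  n <- n1 + n0
  df$weight <- ifelse(df$occ == 1, n / (2 * n1), n / (2 * n0))
  rownames(df) <- NULL
  structure(df, class = c("training_table", "data.frame"),
            predictors = names(stack$layers))
}

#' @export
print.training_table <- function(x, ...) {
  cat(sprintf("training_table: %d rows (%d presences, %d pseudo-absences), %d predictors\n",
              nrow(x), sum(x$occ == 1), sum(x$occ == 0),
              length(attr(x, "predictors"))))
  cat("  predictors:", paste(attr(x, "predictors"), collapse = ", "), "\n")
  invisible(x)
}
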