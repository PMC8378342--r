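# Virtual-species generator: spatially autocorrelated environmental fields
# over a synthetic land-sea template, a configurable niche, presence-only
# sampling, and the climate-scenario deltas used for projection tests.

# Gaussian-kernel smoothing of a matrix by separable convolution with
# reflected-edge padding; `smoothness` is the kernel sigma in cells.
smooth_matrix <- function(m, smoothness) {
  if (smoothness <= 0) return(m)
  r <- max(1L, ceiling(3 * smoothness))
  k <- stats::dnorm(-r:r, sd = smoothness)
  k <- k / sum(k)
  pad_idx <- function(n) c(rev(seq_len(min(r, n))), seq_len(n),
                           n + 1 - rev(seq_len(min(r, n))))
  conv1 <- function(x) {  # columns of x smoothed
    xp <- x[pad_idx(nrow(x)), , drop = FALSE]
    out <- apply(xp, 2L, function(col) stats::filter(col, k, sides = 2))
    out[(r + 1):(r + nrow(x)), , drop = FALSE]
  }
  t(conv1(t(conv1(m))))
}

# seeded smooth standard field (mean ~0, sd ~1 after rescale)
smooth_field <- function(nr, nc, smoothness) {
  z <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), smoothness)
  (z - mean(z)) / stats::sd(z)
}

# two-pass chamfer distance transform: distance (in cells) of each cell to
# the nearest TRUE cell of `target`
chamfer_distance <- function(target) {
  nr <- nrow(target); nc <- ncol(target)
  d <- matrix(Inf, nr, nc)
  d[target] <- 0
  o <- sqrt(2)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i > 1) d[i, j] <- min(d[i, j], d[i - 1, j] + 1)
    if (j > 1) d[i, j] <- min(d[i, j], d[i, j - 1] + 1)
    if (i > 1 && j > 1) d[i, j] <- min(d[i, j], d[i - 1, j - 1] + o)
    if (i > 1 && j < nc) d[i, j] <- min(d[i, j], d[i - 1, j + 1] + o)
  }
  for (i in rev(seq_len(nr))) for (j in rev(seq_len(nc))) {
    if (i < nr) d[i, j] <- min(d[i, j], d[i + 1, j] + 1)
    if (j < nc) d[i, j] <- min(d[i, j], d[i, j + 1] + 1)
    if (i < nr && j < nc) d[i, j] <- min(d[i, j], d[i + 1, j + 1] + o)
    if (i < nr && j > 1) d[i, j] <- min(d[i, j], d[i + 1, j - 1] + o)
  }
  d
}

#' Generate a synthetic environmental stack
#'
#' Builds the six standard marine predictors on a shared grid: a synthetic
#' land-sea boundary (smooth field thresholded at `land_fraction`), distance
#' to shore (`Dshore`, km, chamfer distance from land scaled by the
#' equatorial cell size), ocean depth (`Depth`, m, deepening away from shore
#' plus smooth noise), and smooth spatially autocorrelated fields for mean
#' temperature (`T`, degC, with a poleward-cooling gradient, sea-mean
#' centred on `t_mean`), salinity (`Sal`, PSS), current velocity (`CV`,
#' m/s, non-negative) and ice thickness (`Ice`, m, zero except at a trace of
#' the most poleward cells). Land cells are masked in every layer.
#'
#' @param grid a [grid_spec()]; for tests a coarse grid (e.g. 80x80) is
#'   plenty.
#' @param smoothness correlation length (Gaussian kernel sigma) in cells;
#'   0 gives white noise.
#' @param land_fraction fraction of cells turned into land; default 0.25.
#' @param t_mean,sal_mean,cv_mean sea-mean targets for the dynamic layers;
#'   defaults 22.72 degC, 34.51 PSS, 0.10 m/s.
#' @param seed RNG seed; identical seeds give identical stacks.
#' @return a [layer_stack()] with layers `T`, `Sal`, `CV`, `Ice`, `Depth`,
#'   `Dshore`.
#' @export
generate_env_stack <- function(grid = grid_spec(cell_size = 1),
                               smoothness = 4, land_fraction = 0.25,
                               t_mean = 22.72, sal_mean = 34.51,
                               cv_mean = 0.10, seed = 1L) {
  stopifnot(smoothness >= 0)
  nr <- grid$n_rows; nc <- grid$n_cols
  set.seed(seed)
  land_f <- smooth_field(nr, nc, max(smoothness, 2))
  land <- land_f > stats::quantile(land_f, 1 - land_fraction)
  if (all(land) || !any(land)) stop("degenerate land-sea split")
  sea <- !land

  km_per_cell <- grid$cell_size * 111.2  # at the equator
  dshore <- chamfer_distance(land) * km_per_cell
  depth <- 4200 * (1 - exp(-dshore / 120)) +
    1100 * smooth_field(nr, nc, smoothness)
  depth <- pmax(depth, 2)

  lat <- cell_center(grid, row(land_f), col(land_f))$lat
  lat_grad <- cos(lat * pi / 180)  # 1 at the equator, smaller poleward
  t_anom <- 6 * (lat_grad - mean(lat_grad[sea])) +
    1.5 * smooth_field(nr, nc, smoothness)
  temp <- t_mean + t_anom - mean(t_anom[sea])

  sal <- sal_mean + 0.8 * smooth_field(nr, nc, smoothness)
  sal <- sal + (sal_mean - mean(sal[sea]))

  cv <- pmax(cv_mean + 0.06 * smooth_field(nr, nc, smoothness), 0)

  ice <- pmax(0.5 * (abs(lat) - 0.97 * max(abs(lat))) /
                max(abs(lat)) + 0.02 * smooth_field(nr, nc, smoothness), 0)
  ice[abs(lat) < 0.9 * max(abs(lat))] <- 0

  as_layer <- function(v, name, units) {
    v[land] <- NA_real_
    env_layer(name, v, grid, units = units)
  }
  layer_stack(list(as_layer(temp, "T", "degC"),
                   as_layer(sal, "Sal", "PSS"),
                   as_layer(cv, "CV", "m/s"),
                   as_layer(ice, "Ice", "m"),
                   as_layer(depth, "Depth", "m"),
                   as_layer(dshore, "Dshore", "km")),
              scenario_label = "current")
}

#' Specify one predictor's niche response
#'
#' @param shape `"gaussian"` (optimum + width), `"logistic"` (midpoint +
#'   slope; positive slope = decreasing suitability) or `"flat"`.
#' @param center optimum (gaussian) or midpoint (logistic).
#' @param width gaussian sd or logistic slope scale.
#' @param weight exponent weight in the weighted-product combination.
#' @return a `niche_response` list.
#' @export
niche_response <- function(shape = c("gaussian", "logistic", "flat"),
                           center = 0, width = 1, weight = 1) {
  shape <- match.arg(shape)
  stopifnot(weight >= 0, width != 0 || shape == "flat")
  structure(list(shape = shape, center = center, width = width,
                 weight = weight), class = "niche_response")
}

niche_eval_one <- function(r, x) {
  switch(r$shape,
         gaussian = exp(-0.5 * ((x - r$center) / r$width)^2),
         logistic = 1 / (1 + exp((x - r$center) / r$width)),
         flat = rep(1, length(x)))
}

#' Specify a virtual species' niche
#'
#' Per-predictor responses combined by a weighted product
#' (`suitability = prod(response_i ^ weight_i)` with weights normalised to
#' sum 1), so suitability stays in `[0, 1]`. Presences are sampled by
#' Bernoulli draws with `p = suitability ^ gamma`.
#'
#' @param responses named list of [niche_response()]s (names = layer names).
#' @param gamma sampling exponent, `>= 1`; default 1.
#' @return a `niche_spec`.
#' @export
niche_spec <- function(responses, gamma = 1) {
  stopifnot(gamma >= 1, length(responses) >= 1, !is.null(names(responses)))
  structure(list(responses = responses, gamma = gamma), class = "niche_spec")
}

#' Default nearshore shallow-water niche
#'
#' Mirrors a coastal warm-water delphinid: suitability dominated by distance
#' to shore and ocean depth (logistic preferences for nearshore, shallow
#' cells), moderate temperature and salinity effects (gaussian around the
#' stack's sea means), a weak current-velocity effect, and no ice effect.
#' Relative weights roughly 0.47 (Dshore), 0.44 (Depth), 0.23 (T),
#' 0.14 (Sal), 0.08 (CV), 0 (Ice).
#'
#' @param stack the current [layer_stack()], used to centre the thermal and
#'   haline optima on its sea means.
#' @return a [niche_spec()].
#' @export
default_niche <- function(stack) {
  tab <- stack_table(stack)
  niche_spec(list(
    Dshore = niche_response("logistic", center = 120, width = 35,
                            weight = 0.47),
    Depth = niche_response("logistic", center = 900, width = 250,
                           weight = 0.44),
    T = niche_response("gaussian", center = mean(tab$T),
                       width = 1.6 * stats::sd(tab$T), weight = 0.23),
    Sal = niche_response("gaussian", center = mean(tab$Sal),
                         width = 2.5 * stats::sd(tab$Sal), weight = 0.14),
    CV = niche_response("logistic", center = mean(tab$CV) + 2 * stats::sd(tab$CV),
                        width = 2 * stats::sd(tab$CV), weight = 0.08),
    Ice = niche_response("flat", weight = 0)))
}

# truth suitability per jointly valid cell
niche_suitability <- function(stack, niche) {
  tab <- stack_table(stack)
  missing <- setdiff(names(niche$responses), names(tab))
  if (length(missing))
    stop("niche refers to missing layer(s): ", paste(missing, collapse = ", "))
  w <- vapply(niche$responses, `[[`, 0, "weight")
  if (sum(w) <= 0) stop("niche weights sum to zero")
  w <- w / sum(w)
  s <- rep(1, nrow(tab))
  for (nm in names(niche$responses))
    s <- s * niche_eval_one(niche$responses[[nm]], tab[[nm]])^w[[nm]]
  list(table = tab, suitability = s)
}

#' Generate a virtual species
#'
#' Computes the true suitability of every sea cell from the niche, then
#' samples presence cells without replacement by repeated Bernoulli sweeps
#' (`p = suitability ^ gamma`) until the target count is reached — a
#' presence-only observation process. Presences are placed at cell centres.
#'
#' @param stack a [layer_stack()].
#' @param niche a [niche_spec()]; default [default_niche()].
#' @param n_presences target presence count; default 82.
#' @param truth_threshold threshold defining the true binary range; default
#'   0.5.
#' @param seed RNG seed.
#' @param max_sweeps sampling sweeps before giving up.
#' @return list with `presences` (a [presence_set()]) and `truth` (a
#'   `truth_map`: suitability map, binary map and the generating niche).
#' @export
generate_virtual_species <- function(stack, niche = default_niche(stack),
                                     n_presences = 82, truth_threshold = 0.5,
                                     seed = 1L, max_sweeps = 2000L) {
  ns <- niche_suitability(stack, niche)
  tab <- ns$table
  p <- ns$suitability^niche$gamma
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[attr(tab, "cell")] <- ns$suitability
  suit_map <- structure(list(grid = stack$grid, values = vals,
                             scenario_label = stack$scenario_label),
                        class = "suitability_map")
  truth <- list(suitability = suit_map,
                binary = binarize(suit_map, truth_threshold),
                niche = niche, threshold = truth_threshold)
  class(truth) <- "truth_map"

  candidates <- which(p > 0)
  if (length(candidates) < n_presences)
    stop(sprintf("only %d cells with positive suitability; cannot reach %d presences",
                 length(candidates), n_presences))
  set.seed(seed)
  chosen <- integer()
  sweeps <- 0L
  while (length(chosen) < n_presences) {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps)
      stop(sprintf("presence target unreachable: %d of %d after %d sweeps",
                   length(chosen), n_presences, max_sweeps))
    ord <- sample(candidates)
    hit <- ord[stats::runif(length(ord)) < p[ord]]
    hit <- setdiff(hit, chosen)
    if (length(hit))
      chosen <- c(chosen, hit[seq_len(min(length(hit),
                                          n_presences - length(chosen)))])
  }
  ctr <- cell_center(stack$grid, attr(tab, "row")[chosen],
                     attr(tab, "col")[chosen])
  list(presences = presence_set(ctr$lon, ctr$lat), truth = truth)
}

#' @export
print.truth_map <- function(x, ...) {
  v <- x$suitability$values[!is.na(x$suitability$values)]
  cat(sprintf("truth_map: %d sea cells, mean suitability %.3f, %d suitable at t = %g\n",
              length(v), mean(v),
              sum(x$binary$values, na.rm = TRUE), x$threshold))
  invisible(x)
}

#' Default climate-scenario deltas
#'
#' The eight RCP x horizon scenarios with the mean additive shifts of the
#' dynamic predictors (temperature, salinity, current velocity, ice
#' thickness); depth and distance to shore are static. For example the
#' pessimistic RCP8.5 pathway warms by +1.10 degC by the 2050s and
#' +2.87 degC by the 2100s.
#'
#' @return named list of eight [scenario_delta()]s.
#' @export
default_scenarios <- function() {
  mk <- function(id, T, Sal, CV, Ice = 0)
    scenario_delta(id, T = T, Sal = Sal, CV = CV, Ice = Ice)
  out <- list(
    RCP26_2050s = mk("RCP26_2050s", T = 0.72, Sal = -0.061, CV = 0.00),
    RCP45_2050s = mk("RCP45_2050s", T = 0.96, Sal = -0.07, CV = 0.24),
    RCP60_2050s = mk("RCP60_2050s", T = 0.77, Sal = -0.07, CV = 0.25),
    RCP85_2050s = mk("RCP85_2050s", T = 1.10, Sal = -0.07, CV = 0.00),
    RCP26_2100s = mk("RCP26_2100s", T = 0.63, Sal = -0.09, CV = 0.24),
    RCP45_2100s = mk("RCP45_2100s", T = 1.21, Sal = -0.13, CV = 0.13),
    RCP60_2100s = mk("RCP60_2100s", T = 1.68, Sal = -0.16, CV = 0.13),
    RCP85_2100s = mk("RCP85_2100s", T = 2.87, Sal = -0.26, CV = 0.23))
  out
}
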