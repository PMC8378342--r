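# Gridded environmental layers: grid geometry, layer and stack containers,
# ASCII-grid I/O, collinearity screening.

#' Define a regular geographic grid
#'
#' A `grid_spec` describes a regular longitude/latitude grid in EPSG:4326.
#' Cell centres sit at `min + (i - 0.5) * cell_size`; cells are half-open
#' intervals so a point on the upper longitude/latitude bound falls outside
#' the grid. Longitudes may be given in [-180, 360) and are normalised to
#' [-180, 180). The default extent is the Indo-Pacific study region
#' (50E-180E, 50S-50N) at 5 arc-minute resolution.
#'
#' @param lon_min,lon_max,lat_min,lat_max extent in decimal degrees.
#' @param cell_size cell edge in degrees; default 1/12 degree (5 arc-minutes).
#' @return an object of class `grid_spec` with fields `n_rows` and `n_cols`.
#' @examples
#' g <- grid_spec(0, 10, 0, 5, cell_size = 0.5)
#' g$n_cols  # 20
#' @export
grid_spec <- function(lon_min = 50, lon_max = 180, lat_min = -50, lat_max = 50,
                      cell_size = 1 / 12) {
  stopifnot(is.finite(lon_min), is.finite(lon_max), is.finite(lat_min),
            is.finite(lat_max), cell_size > 0)
  lon_min <- normalize_lon(lon_min)
  # keep lon_max = 180 as-is (normalising would wrap it to -180)
  if (lon_max > 180 && lon_max < 360) lon_max <- lon_max - 360
  if (lon_max <= lon_min) stop("lon_max must exceed lon_min after normalisation")
  if (lat_max <= lat_min) stop("lat_max must exceed lat_min")
  if (lat_min < -90 || lat_max > 90) stop("latitudes must lie in [-90, 90]")
  n_cols <- as.integer(round((lon_max - lon_min) / cell_size))
  n_rows <- as.integer(round((lat_max - lat_min) / cell_size))
  if (n_cols < 1L || n_rows < 1L) stop("extent smaller than one cell")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 cell_size = cell_size, n_rows = n_rows, n_cols = n_cols),
            class = "grid_spec")
}

normalize_lon <- function(lon) {
  out <- lon
  out[out >= 180] <- out[out >= 180] - 360
  out[out < -180] <- out[out < -180] + 360
  out
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, cell %.6g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  extent: lon [%g, %g), lat [%g, %g)\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(c(a$lon_min - b$lon_min, a$lat_min - b$lat_min,
            a$cell_size - b$cell_size)) < tol) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Locate points on a grid
#'
#' Maps point coordinates to the (row, col) of their containing cells;
#' row 1 is the northern edge. Points outside the half-open extent get `NA`.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat point coordinates in degrees.
#' @return list with integer vectors `row` and `col`.
#' @export
cell_index <- function(grid, lon, lat) {
  lon <- normalize_lon(lon)
  col <- floor((lon - grid$lon_min) / grid$cell_size) + 1
  # half-open in latitude too: lat_min belongs to the last row, lat_max is out
  row <- grid$n_rows - floor((lat - grid$lat_min) / grid$cell_size)
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates
#'
#' @param grid a [grid_spec()].
#' @param row,col cell indices (row 1 = north).
#' @return list with `lon` and `lat` of the cell centres.
#' @export
cell_center <- function(grid, row, col) {
  list(lon = grid$lon_min + (col - 0.5) * grid$cell_size,
       lat = grid$lat_max - (row - 0.5) * grid$cell_size)
}

#' Construct an environmental layer
#'
#' @param name predictor identifier (e.g. `"T"`, `"Sal"`, `"Depth"`).
#' @param values numeric matrix (`n_rows` x `n_cols`, row 1 = north);
#'   `NA` marks masked (land / nodata) cells.
#' @param grid a [grid_spec()].
#' @param units free-text units label.
#' @return an object of class `env_layer`.
#' @export
env_layer <- function(name, values, grid, units = "") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("layer '%s': values are %dx%d but grid is %dx%d",
                 name, nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  structure(list(name = name, units = units, grid = grid,
                 values = values),
            class = "env_layer")
}

#' @export
print.env_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("env_layer '%s'%s: %d/%d valid cells, range [%.4g, %.4g]\n",
              x$name, if (nzchar(x$units)) paste0(" (", x$units, ")") else "",
              length(v), length(x$values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

valid_mask <- function(layer) !is.na(layer$values)

#' Bundle environmental layers into a stack
#'
#' All layers must share one grid; the stack's joint valid mask is the
#' intersection of the member masks (so it can only shrink as layers are
#' added).
#'
#' @param ... `env_layer` objects, or a single list of them.
#' @param scenario_label free-text label, e.g. `"current"` or `"RCP85_2100s"`.
#' @return an object of class `layer_stack`.
#' @export
layer_stack <- function(..., scenario_label = "current") {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "env_layer"))
    layers <- layers[[1L]]
  if (!length(layers)) stop("empty stack")
  if (!all(vapply(layers, inherits, TRUE, "env_layer")))
    stop("all elements must be env_layer objects")
  nms <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate layer names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  g <- layers[[1L]]$grid
  for (l in layers[-1L]) if (!same_grid(g, l$grid))
    stop(sprintf("grid mismatch: layer '%s' (%dx%d) vs '%s' (%dx%d)",
                 layers[[1L]]$name, g$n_rows, g$n_cols,
                 l$name, l$grid$n_rows, l$grid$n_cols))
  names(layers) <- nms
  structure(list(layers = layers, grid = g, scenario_label = scenario_label),
            class = "layer_stack")
}

#' @export
names.layer_stack <- function(x) names(x$layers)

#' @export
`[[.layer_stack` <- function(x, i) x$layers[[i]]

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer_stack '%s': %d layers on %dx%d grid [%s]\n",
              x$scenario_label, length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  joint valid cells: %d\n", sum(joint_mask(x))))
  invisible(x)
}

#' Joint validity mask of a stack
#'
#' @param stack a [layer_stack()].
#' @return logical matrix; `TRUE` where every member layer is valid.
#' @export
joint_mask <- function(stack) {
  m <- valid_mask(stack$layers[[1L]])
  for (l in stack$layers[-1L]) m <- m & valid_mask(l)
  m
}

#' Predictor table of a stack's valid cells
#'
#' Returns the predictor values of every jointly valid cell as a data.frame
#' (column-major cell order), with the cells' `row`, `col` and linear `cell`
#' indices in attributes.
#'
#' @param stack a [layer_stack()].
#' @param mask logical matrix selecting cells; default the joint mask.
#' @return data.frame, one column per layer.
#' @export
stack_table <- function(stack, mask = joint_mask(stack)) {
  idx <- which(mask)
  df <- as.data.frame(lapply(stack$layers, function(l) l$values[idx]))
  names(df) <- names(stack$layers)
  rc <- arrayInd(idx, dim(mask))
  attr(df, "row") <- rc[, 1L]
  attr(df, "col") <- rc[, 2L]
  attr(df, "cell") <- idx
  df
}

#' Extract predictor values at point locations
#'
#' Points on masked or out-of-extent cells yield `NA` rows.
#'
#' @param stack a [layer_stack()].
#' @param lon,lat point coordinates in degrees.
#' @return data.frame, one column per layer, one row per point.
#' @export
extract_values <- function(stack, lon, lat) {
  rc <- cell_index(stack$grid, lon, lat)
  out <- lapply(stack$layers, function(l) {
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(rc$row)
    v[ok] <- l$values[cbind(rc$row[ok], rc$col[ok])]
    v
  })
  df <- as.data.frame(out)
  names(df) <- names(stack$layers)
  df
}

#' Read a single-band ASCII raster grid
#'
#' Reads the ESRI ASCII grid format (plain-text header + matrix of values),
#' the package's on-disk raster representation. Coordinates are taken to be
#' geographic (EPSG:4326). `NODATA_value` cells become masked cells.
#'
#' @param path path to a `.asc` file.
#' @param name predictor name to give the layer; defaults to the file stem.
#' @param units optional units label.
#' @return an [env_layer()].
#' @export
read_layer <- function(path, name = NULL, units = "") {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("truncated ASCII grid: ", path)
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    } else {
      seek(con, pos); break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing ", paste(setdiff(need, names(hdr)), collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcenter)) hdr$xllcorner <- hdr$xllcenter - cs / 2
  if (!is.null(hdr$yllcenter)) hdr$yllcorner <- hdr$yllcenter - cs / 2
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(con, what = numeric(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid %s: expected %d values, found %d",
                 path, nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # file rows run N -> S
  m[m == nodata] <- NA_real_
  g <- grid_spec(lon_min = hdr$xllcorner, lon_max = hdr$xllcorner + nc * cs,
                 lat_min = hdr$yllcorner, lat_max = hdr$yllcorner + nr * cs,
                 cell_size = cs)
  env_layer(name, m, g, units = units)
}

#' Write a layer as an ASCII raster grid
#'
#' @param layer an [env_layer()].
#' @param path output path (`.asc`).
#' @param nodata sentinel written for masked cells.
#' @param digits significant digits for values.
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path, nodata = -9999, digits = 9) {
  g <- layer$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$lon_min),
           sprintf("yllcorner %.10g", g$lat_min),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  m <- layer$values
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a stack from a manifest
#'
#' The manifest is a YAML file mapping layer names to file paths (and
#' optionally units): `T: {path: T.asc, units: degC}` or simply
#' `T: T.asc`. Relative paths are resolved against the manifest's directory.
#'
#' @param manifest path to the YAML manifest.
#' @param scenario_label label for the stack.
#' @return a [layer_stack()].
#' @export
read_stack <- function(manifest, scenario_label = "current") {
  spec <- yaml::read_yaml(manifest)
  base <- dirname(manifest)
  layers <- lapply(names(spec), function(nm) {
    ent <- spec[[nm]]
    if (is.character(ent)) ent <- list(path = ent)
    p <- ent$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_layer(p, name = nm, units = if (is.null(ent$units)) "" else ent$units)
  })
  layer_stack(layers, scenario_label = scenario_label)
}

#' Write a stack to a directory with a manifest
#'
#' @param stack a [layer_stack()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- list()
  for (nm in names(stack)) {
    f <- paste0(nm, ".asc")
    write_layer(stack[[nm]], file.path(dir, f))
    spec[[nm]] <- list(path = f, units = stack[[nm]]$units)
  }
  manifest <- file.path(dir, "manifest.yml")
  yaml::write_yaml(spec, manifest)
  invisible(manifest)
}

#' Pairwise Pearson correlations between stack layers
#'
#' Correlations are computed over all jointly valid cells, or over a seeded
#' random subsample of them. A constant layer has no defined correlation and
#' its entries are reported as `NA` (not 0).
#'
#' @param stack a [layer_stack()] with at least two layers.
#' @param sample_cells optional integer; number of jointly valid cells to
#'   subsample.
#' @param seed RNG seed used when subsampling.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(stack, sample_cells = NULL, seed = 1L) {
  if (length(stack$layers) < 2L) stop("need at least two layers")
  df <- stack_table(stack)
  if (nrow(df) < 3L) stop("need at least three jointly valid cells")
  if (!is.null(sample_cells) && sample_cells < nrow(df)) {
    set.seed(seed)
    df <- df[sample.int(nrow(df), sample_cells), , drop = FALSE]
  }
  sds <- vapply(df, stats::sd, 0)
  m <- suppressWarnings(stats::cor(df, method = "pearson"))
  m[sds == 0, ] <- NA_real_
  m[, sds == 0] <- NA_real_
  diag(m) <- 1
  m
}

#' Greedy selection of mutually low-correlation layers
#'
#' Scans layers in priority order and retains a layer iff its absolute
#' correlation with every already-retained layer is below `threshold`.
#' Layers with undefined correlations (constant layers) are never retained.
#'
#' @param corr symmetric correlation matrix with dimnames.
#' @param threshold collinearity cutoff in (0, 1]; default 0.7.
#' @param priority character vector ordering all layers; earlier wins.
#' @return character vector of retained layer names.
#' @export
select_uncorrelated <- function(corr, threshold = 0.7,
                                priority = rownames(corr)) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(rownames(corr))) stop("corr must have dimnames")
  if (!setequal(priority, rownames(corr)))
    stop("priority must cover exactly the layers in corr")
  kept <- character()
  others <- function(nm) setdiff(rownames(corr), nm)
  for (nm in priority) {
    if (nrow(corr) > 1 && all(is.na(corr[nm, others(nm)])))
      next  # constant layer: correlations undefined, never retained
    r <- corr[nm, kept]
    if (length(kept) && anyNA(r)) next
    if (all(abs(r) < threshold)) kept <- c(kept, nm)
  }
  kept
}
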