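# Shared fixtures: tiny synthetic stacks, toy training tables, and minimal
# stand-in models for contract tests.

tiny_grid <- function(n = 30, cell = 1) grid_spec(100, 100 + n * cell,
                                                  -n * cell / 2, n * cell / 2,
                                                  cell_size = cell)

tiny_stack <- function(seed = 1, n = 30) {
  generate_env_stack(tiny_grid(n), seed = seed)
}

# linearly separable two-predictor table: presences at x1 ~ +2, absences ~ -2
toy_table <- function(n_per_class = 30, seed = 1, sep = 2) {
  set.seed(seed)
  x1 <- c(rnorm(n_per_class, sep, 0.3), rnorm(n_per_class, -sep, 0.3))
  x2 <- rnorm(2 * n_per_class)
  occ <- rep(c(1, 0), each = n_per_class)
  df <- data.frame(lon = 0, lat = 0, x1 = x1, x2 = x2, occ = occ, weight = 1)
  structure(df, class = c("training_table", "data.frame"),
            predictors = c("x1", "x2"))
}

# table with no predictor-response relationship
null_table <- function(n_per_class = 100, seed = 1) {
  set.seed(seed)
  df <- data.frame(lon = 0, lat = 0,
                   x1 = rnorm(2 * n_per_class), x2 = rnorm(2 * n_per_class),
                   occ = rep(c(1, 0), each = n_per_class), weight = 1)
  df <- df[sample.int(nrow(df)), ]
  rownames(df) <- NULL
  structure(df, class = c("training_table", "data.frame"),
            predictors = c("x1", "x2"))
}

# degenerate model classes for predict-contract tests
registerS3method("predict", "constant_model",
                 function(object, newdata, ...) rep(object$value, nrow(newdata)),
                 envir = asNamespace("stats"))
constant_model <- function(value, predictors = "x1")
  structure(list(value = value, all_predictors = predictors),
            class = "constant_model")

registerS3method("predict", "identity_model",
                 function(object, newdata, ...)
                   pmin(pmax(newdata[[object$var]], 0), 1),
                 envir = asNamespace("stats"))
identity_model <- function(var = "x1", predictors = var)
  structure(list(var = var, all_predictors = predictors),
            class = "identity_model")

# random binary map pair on a shared mask
random_binary_pair <- function(nr = 20, nc = 20, p_valid = 0.9, seed = 1) {
  set.seed(seed)
  mask <- matrix(runif(nr * nc) < p_valid, nr, nc)
  mk <- function() {
    v <- matrix(NA_real_, nr, nc)
    v[mask] <- rbinom(sum(mask), 1, 0.5)
    binary_map(v)
  }
  cur <- mk()
  if (sum(cur$values, na.rm = TRUE) == 0) cur$values[which(mask)[1]] <- 1
  list(current = cur, future = mk())
}
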