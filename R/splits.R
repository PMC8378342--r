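# Repeated stratified k-fold splits and the cross-validated evaluation loop.

# one stratified fold-label vector (1..k) for a 0/1 response
make_fold_vector <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' Repeated stratified k-fold split assignments
#'
#' Per repetition, rows are partitioned into `k` folds stratified by the
#' response so each fold keeps the global class ratio (within one member).
#' Each fit trains on the remaining `(k - 1) / k` of the data — 80% for the
#' default fivefold design — and is evaluated on the withheld fold.
#'
#' @param table a training table (or any data.frame with an `occ` column).
#' @param k number of folds; default 5.
#' @param repetitions number of repetitions; default 10.
#' @param seed master seed; each repetition uses a derived sub-seed.
#' @return integer matrix `nrow(table)` x `repetitions` of fold labels in
#'   `1..k`.
#' @export
make_splits <- function(table, k = 5, repetitions = 10, seed = 1L) {
  stopifnot(k >= 2, repetitions >= 1)
  y <- table$occ
  if (any(table(y) < k))
    stop(sprintf("each class needs at least k = %d members", k))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)
  out <- vapply(seq_len(repetitions),
                function(r) make_fold_vector(y, k, sub_seeds[r]),
                integer(length(y)))
  colnames(out) <- paste0("rep", seq_len(repetitions))
  out
}

#' Cross-validated evaluation of the learner zoo
#'
#' Runs the repeated stratified k-fold design: for every repetition, fold
#' and algorithm, fits on the training folds and scores the withheld fold,
#' recording the TSS-maximising threshold, the TSS at that threshold, and
#' the AUC (all computed on unweighted held-out counts).
#'
#' @param table a [build_training_table()] result.
#' @param algorithms algorithm ids to evaluate; default all ten.
#' @param k,repetitions cross-validation design; defaults 5 and 10.
#' @param seed master seed, fanned out deterministically to splits and
#'   stochastic learners.
#' @param hyper optional named list of per-algorithm hyperparameter
#'   overrides, e.g. `list(GBM = list(nrounds = 100))`.
#' @param splits optional precomputed [make_splits()] matrix.
#' @param verbose print one progress line per repetition.
#' @return data.frame of evaluation records: `algorithm`, `repetition`,
#'   `fold`, `tss`, `auc`, `threshold`.
#' @export
evaluate_sdms <- function(table, algorithms = sdm_algorithms(), k = 5,
                          repetitions = 10, seed = 1L, hyper = list(),
                          splits = NULL, verbose = FALSE) {
  algorithms <- match.arg(algorithms, sdm_algorithms(), several.ok = TRUE)
  if (is.null(splits))
    splits <- make_splits(table, k = k, repetitions = repetitions,
                          seed = seed + 1L)
  repetitions <- ncol(splits)
  k <- max(splits)
  set.seed(seed + 2L)
  fit_seeds <- array(sample.int(.Machine$integer.max - 1L,
                                length(algorithms) * repetitions * k),
                     dim = c(length(algorithms), repetitions, k))
  rec <- vector("list", length(algorithms) * repetitions * k)
  i <- 0L
  for (r in seq_len(repetitions)) {
    for (f in seq_len(k)) {
      train <- which(splits[, r] != f)
      test <- which(splits[, r] == f)
      for (a in seq_along(algorithms)) {
        alg <- algorithms[a]
        m <- fit_sdm(alg, table, rows = train, seed = fit_seeds[a, r, f],
                     hyper = if (is.null(hyper[[alg]])) list() else hyper[[alg]])
        p <- predict(m, as.data.frame(table)[test, , drop = FALSE])
        y <- table$occ[test]
        opt <- optimal_threshold(p, y)
        i <- i + 1L
        rec[[i]] <- data.frame(algorithm = alg, repetition = r, fold = f,
                               tss = opt$tss, auc = auc(p, y),
                               threshold = opt$threshold)
      }
    }
    if (verbose)
      message(sprintf("evaluate_sdms: repetition %d/%d done", r, repetitions))
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}
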