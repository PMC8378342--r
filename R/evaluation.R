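# Presence-absence skill metrics from first principles: confusion matrices,
# TSS, rank-based AUC, TSS-maximising thresholds, and retention gating.

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
}

#' Confusion matrix at a threshold
#'
#' A score is predicted positive iff `score >= t` (ties at the threshold go
#' to the positive class). Optional case weights give weighted (real-valued)
#' counts.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 vector of the same length; both classes required.
#' @param t threshold.
#' @param weights optional positive case weights.
#' @return an object of class `confusion` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at <- function(scores, labels, t, weights = NULL) {
  stopifnot(length(scores) == length(labels))
  check_labels(labels)
  if (is.null(weights)) weights <- rep(1, length(scores))
  pos <- scores >= t
  structure(list(TP = sum(weights[pos & labels == 1]),
                 FP = sum(weights[pos & labels == 0]),
                 TN = sum(weights[!pos & labels == 0]),
                 FN = sum(weights[!pos & labels == 1])),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion: TP=%g FP=%g TN=%g FN=%g (sens=%.3f spec=%.3f)\n",
              x$TP, x$FP, x$TN, x$FN,
              x$TP / (x$TP + x$FN), x$TN / (x$TN + x$FP)))
  invisible(x)
}

#' True skill statistic
#'
#' TSS = sensitivity + specificity - 1; ranges over `[-1, 1]`, is 0 for a
#' no-skill classifier and is unaffected by prevalence.
#'
#' @param c a [confusion_at()] result.
#' @return TSS value.
#' @export
tss <- function(c) {
  if (c$TP + c$FN <= 0 || c$TN + c$FP <= 0)
    stop("undefined sensitivity or specificity: empty class margin")
  c$TP / (c$TP + c$FN) + c$TN / (c$TN + c$FP) - 1
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted half: the probability
#' that a random presence outscores a random absence. Equals the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_labels(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# TSS at every candidate threshold, vectorised. Candidates are 0, 1, and the
# midpoints between consecutive distinct sorted scores.
tss_curve <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- unique(c(0, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, 1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  # for each candidate t: TP = #positives with score >= t
  tp <- vapply(cand, function(t) sum(labels == 1 & scores >= t), 0)
  fp <- vapply(cand, function(t) sum(labels == 0 & scores >= t), 0)
  data.frame(threshold = cand, tss = tp / n1 + (n0 - fp) / n0 - 1)
}

#' TSS-maximising threshold
#'
#' Scans the candidate set (midpoints between consecutive distinct scores,
#' plus 0 and 1) and returns the threshold with maximal TSS; ties are broken
#' toward the smallest maximising threshold.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 vector; both classes required.
#' @return list with `threshold` and `tss`.
#' @export
optimal_threshold <- function(scores, labels) {
  check_labels(labels)
  cur <- tss_curve(scores, labels)
  best <- which.max(cur$tss)  # which.max returns the first (smallest) maximiser
  list(threshold = cur$threshold[best], tss = cur$tss[best])
}

#' Aggregate fold metrics and gate algorithms
#'
#' Averages TSS and AUC per algorithm over all repetitions x folds and
#' retains an algorithm iff mean TSS strictly exceeds `tss_min` AND mean AUC
#' strictly exceeds `auc_min`.
#'
#' @param records data.frame with columns `algorithm`, `repetition`, `fold`,
#'   `tss`, `auc` (and typically `threshold`), as produced by
#'   [evaluate_sdms()].
#' @param tss_min,auc_min retention gates; defaults 0.80 and 0.85.
#' @return list with `means` (data.frame: algorithm, tss, auc, retained) and
#'   `retained` (character vector of algorithm ids).
#' @export
aggregate_and_gate <- function(records, tss_min = 0.80, auc_min = 0.85) {
  stopifnot(all(c("algorithm", "tss", "auc") %in% names(records)))
  alg <- unique(records$algorithm)
  means <- data.frame(
    algorithm = alg,
    tss = vapply(alg, function(a) mean(records$tss[records$algorithm == a]), 0),
    auc = vapply(alg, function(a) mean(records$auc[records$algorithm == a]), 0),
    row.names = NULL)
  means$retained <- means$tss > tss_min & means$auc > auc_min
  list(means = means, retained = means$algorithm[means$retained])
}
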