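#' Precision, recall and F1 at a score threshold
#'
#' Predictions are `score >= threshold`. Precision is `TP/(TP+FP)`, reported
#' as 1 with a `vacuous` attribute when nothing is predicted positive (0/0);
#' recall is `TP/(TP+FN)`; F1 is their harmonic mean, 0 when both are 0.
#'
#' @param scores Numeric vector.
#' @param labels Vector in \{-1, +1\} (>= 1 positive required).
#' @param threshold Decision threshold (default 0, the SVM boundary).
#' @return Named numeric vector `(precision, recall, f1)`; attribute
#'   `vacuous` is `TRUE` when no positive prediction was made.
#' @export
pr_f1 <- function(scores, labels, threshold = 0) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) abort("labels must be +1/-1")
  if (!any(labels == 1)) abort("no positive labels: recall undefined")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == -1)
  fn <- sum(!pred & labels == 1)
  vacuous <- (tp + fp) == 0L
  precision <- if (vacuous) 1 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(c(precision = precision, recall = recall, f1 = f1),
            vacuous = vacuous)
}

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counted one half (the normalized Mann-Whitney
#' U statistic), computed from midranks.
#'
#' @param scores Numeric vector.
#' @param labels Vector in \{-1, +1\}; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) abort("labels must be +1/-1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) abort("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (rectangular) integration over descending unique score
#' thresholds: `sum_k (R_k - R_{k-1}) * P_k`. Preferred over AUC when true
#' edges are rare.
#'
#' @inheritParams auc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) abort("labels must be +1/-1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || n_pos == length(labels)) abort("both classes required for AUPR")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == 1
  cum_tp <- cumsum(pos)
  cum_pp <- seq_along(s)
  last_of_level <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cum_tp[last_of_level]
  pp <- cum_pp[last_of_level]
  prec <- tp / pp
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a decision-score matrix against regulation labels
#'
#' Per-TF precision/recall/F1 at a threshold plus AUC and AUPR, and their
#' unweighted means over evaluable TFs (>= 1 positive, both classes present,
#' column not skipped or failed).
#'
#' @param ds A [score_matrix()].
#' @param R A `regulation_matrix` on the same genes/TFs; its labels are the
#'   evaluation truth.
#' @param threshold Classification threshold (default 0).
#' @param exclude_training_positives When `TRUE`, genes whose positive label
#'   was revealed to training (`known_mask`) are removed before scoring a
#'   column, so metrics reflect recovery of *hidden* true edges only.
#' @return An `eval_report`: list with `per_tf` (data frame), `average`
#'   (named means), `threshold`, `n_evaluated`, `n_excluded`.
#' @export
cv_report <- function(ds, R, threshold = 0, exclude_training_positives = FALSE) {
  if (!identical(rownames(ds), rownames(R))) abort("gene sets do not match")
  tf_ids <- intersect(colnames(ds), colnames(R))
  if (!length(tf_ids)) abort("no shared TF columns")
  st <- attr(ds, "status")
  km <- attr(R, "known_mask")
  rows <- list()
  excluded <- character()
  for (tf in tf_ids) {
    if (!st[tf] %in% c("ok", "all-data")) { excluded <- c(excluded, tf); next }
    y <- unclass(R)[, tf]
    s <- unclass(ds)[, tf]
    keep <- rep(TRUE, length(y))
    if (exclude_training_positives && !is.null(km)) {
      keep <- !(km[, tf] & y == 1)
    }
    y <- y[keep]; s <- s[keep]
    if (sum(y == 1) < 1L || sum(y == -1) < 1L || anyNA(s)) {
      excluded <- c(excluded, tf); next
    }
    pr <- pr_f1(s, y, threshold)
    rows[[tf]] <- data.frame(tf = tf, precision = pr[["precision"]],
                             recall = pr[["recall"]], f1 = pr[["f1"]],
                             auc = auc(s, y), aupr = aupr(s, y),
                             n_pos = sum(y == 1), n_neg = sum(y == -1),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) abort("no evaluable TF column")
  per_tf <- do.call(rbind, rows)
  rownames(per_tf) <- NULL
  avg <- colMeans(per_tf[, c("precision", "recall", "f1", "auc", "aupr")])
  structure(list(per_tf = per_tf, average = avg, threshold = threshold,
                 n_evaluated = nrow(per_tf), n_excluded = length(excluded),
                 excluded = excluded),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report over %d TF(s) at threshold %g (%d excluded)\n",
              x$n_evaluated, x$threshold, x$n_excluded))
  cat(sprintf("  avg precision %.4f  recall %.4f  F1 %.4f  AUC %.4f  AUPR %.4f\n",
              x$average[["precision"]], x$average[["recall"]],
              x$average[["f1"]], x$average[["auc"]], x$average[["aupr"]]))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per TF plus a final `average` row.
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  df <- report$per_tf
  avg <- data.frame(tf = "average", t(report$average),
                    n_pos = NA, n_neg = NA, stringsAsFactors = FALSE)
  names(avg) <- names(df)
  write.table(rbind(df, avg), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Parallel performance metrics: speedup, efficiency, redundancy, quality
#'
#' From sequential wall time `T1`, parallel wall time `Tj` on `j` workers and
#' abstract operation counts `O1`/`Oj`:
#' speedup `S = T1/Tj`, efficiency `E = S/j`, redundancy `R = Oj/O1`, quality
#' `Q = S*E/R`.
#'
#' @param T1 Sequential wall time (seconds, > 0).
#' @param Tj Parallel wall time on `j` workers (> 0).
#' @param j Worker count (>= 1).
#' @param O1,Oj Operation counts in the two modes (default equal, > 0).
#' @return Named list `(S, E, R, Q)`.
#' @examples
#' perf_metrics(T1 = 80, Tj = 10, j = 8)  # ideal: S = 8, E = 1, R = 1, Q = 8
#' @export
perf_metrics <- function(T1, Tj, j, O1 = 1, Oj = O1) {
  vals <- c(T1 = T1, Tj = Tj, j = j, O1 = O1, Oj = Oj)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all performance-record fields must be positive")
  }
  S <- T1 / Tj
  E <- S / j
  R <- Oj / O1
  list(S = S, E = E, R = R, Q = S * E / R)
}
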