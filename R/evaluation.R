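# Evaluation protocol: stratified k-fold CV, cutoff sweep maximizing the
# average F-measure, rank-statistic AUC, random-order baseline and
# single-feature ablation.

#' Stratified cross-validation folds
#'
#' Partitions example indices into `k` folds with per-fold class ratios
#' within one example of the global ratio; deterministic given `seed`.
#'
#' @param labels Character vector of POSITIVE/NEGATIVE labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer RNG seed.
#' @return List of `k` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 42) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  for (cl in unique(labels)) {
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer than k = ", k, " examples")
  }
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[assign_to == j])
  }
  lapply(folds, sort)
}

#' Precision/recall/F at a top-k cutoff
#'
#' The top `k` ranked items are classified positive, the rest negative:
#' P = TP/k, R = TP/n_pos, F = 2PR/(P+R) (0 when both are 0). Values are
#' percentages.
#'
#' @param ranked_labels Logical (or POSITIVE/NEGATIVE character) vector of
#'   gold labels in rank order, best first.
#' @param k Cutoff, `1 <= k <= length(ranked_labels)`.
#' @return Named numeric vector `precision`, `recall`, `f_measure`.
#' @export
prf_at_cutoff <- function(ranked_labels, k) {
  pos <- as_logical_labels(ranked_labels)
  n <- length(pos)
  stopifnot(k >= 1, k <= n)
  tp <- sum(pos[seq_len(k)])
  p <- tp / k
  r <- if (sum(pos) > 0) tp / sum(pos) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = 100 * p, recall = 100 * r, f_measure = 100 * f)
}

as_logical_labels <- function(x) {
  if (is.logical(x)) return(x)
  x == "POSITIVE"
}

#' Best cutoff by averaged F-measure across folds
#'
#' Sweeps cutoff fractions (every attained `i / fold size`); for each
#' fraction the cutoff in fold `j` is `round(fraction * n_j)` (at least 1),
#' the F-measures are averaged across folds, and the fraction with the
#' highest average F is selected (ties go to the smallest fraction).
#'
#' @param fold_rankings List with one element per fold: gold labels in rank
#'   order (logical or POSITIVE/NEGATIVE).
#' @return List with `cutoff_fraction`, `precision`, `recall`, `f_measure`
#'   (averages across folds at the selected fraction) and the full sweep
#'   `curve` data.frame.
#' @export
best_cutoff_f <- function(fold_rankings) {
  folds <- lapply(fold_rankings, as_logical_labels)
  sizes <- lengths(folds)
  fracs <- sort(unique(unlist(lapply(sizes, function(n) seq_len(n) / n))))
  curve <- data.frame(fraction = fracs, precision = NA_real_,
                      recall = NA_real_, f_measure = NA_real_)
  for (i in seq_along(fracs)) {
    prf <- vapply(folds, function(lab) {
      k <- max(1L, round(fracs[i] * length(lab)))
      prf_at_cutoff(lab, min(k, length(lab)))
    }, numeric(3))
    curve$precision[i] <- mean(prf["precision", ])
    curve$recall[i] <- mean(prf["recall", ])
    curve$f_measure[i] <- mean(prf["f_measure", ])
  }
  best <- which.max(curve$f_measure)   # first max = smallest fraction
  list(cutoff_fraction = curve$fraction[best],
       precision = curve$precision[best], recall = curve$recall[best],
       f_measure = curve$f_measure[best], curve = curve)
}

#' Rank-statistic AUC
#'
#' Mann-Whitney AUC of scores against binary labels: the probability that
#' a random positive outscores a random negative, ties counting one half.
#' Returned as a percentage.
#'
#' @param scores Numeric score vector.
#' @param labels Logical or POSITIVE/NEGATIVE labels.
#' @return AUC in `[0, 100]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- as_logical_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores)
  100 * (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random-order baseline
#'
#' Draws i.i.d. uniform scores for `n_pos + n_neg` labeled items, applies
#' the best-cutoff-F protocol and the AUC to the resulting ranking, and
#' averages over `reps` orderings. With the cutoff free to maximize F the
#' selected cutoff sits near the bottom of the list, so recall approaches
#' 100% and precision approaches the positive-class rate.
#'
#' @param n_pos,n_neg Class composition.
#' @param reps Number of random orderings (default 100).
#' @param seed Integer RNG seed.
#' @return List with averaged `precision`, `recall`, `f_measure`, `auc`,
#'   plus `n_pos`, `n_neg`, `reps`, `seed`.
#' @export
random_order_baseline <- function(n_pos, n_neg, reps = 100, seed = 42) {
  stopifnot(reps >= 1, n_pos >= 1, n_neg >= 1)
  set.seed(seed)
  labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  acc <- matrix(NA_real_, nrow = reps, ncol = 4,
                dimnames = list(NULL, c("precision", "recall", "f_measure",
                                        "auc")))
  for (i in seq_len(reps)) {
    scores <- stats::runif(n_pos + n_neg)
    ranked <- labels[order(-scores)]
    best <- best_cutoff_f(list(ranked))
    acc[i, ] <- c(best$precision, best$recall, best$f_measure,
                  auc_score(scores, labels))
  }
  out <- as.list(colMeans(acc))
  c(out, list(n_pos = n_pos, n_neg = n_neg, reps = reps, seed = seed))
}

#' Cross-validated evaluation of the ranker
#'
#' Stratified k-fold protocol: the model is fitted on the training folds,
#' held-out candidates are ranked, the top-k cutoff maximizing the average
#' F across folds is selected, and the AUC is averaged over folds.
#' Optionally repeats the protocol within each event type.
#'
#' @param features Labeled feature data.frame.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for fold assignment (default 42).
#' @param per_event Also evaluate per event type where both classes have
#'   at least `k` examples (default FALSE).
#' @param ... Passed to [fit_evidence_model()].
#' @return An `eval_report` list: `precision`, `recall`, `f_measure`,
#'   `auc` (percentages), `cutoff_fraction`, `n_pos`, `n_neg`, `seed`, and
#'   `per_event` (data.frame or NULL).
#' @export
cross_validate <- function(features, k = 5, seed = 42, per_event = FALSE,
                           ...) {
  rep_main <- cv_once(features, k, seed, ...)
  per_event_df <- NULL
  if (per_event) {
    rows <- list()
    for (et in intersect(event_types(), unique(features$event_type))) {
      sub <- features[features$event_type == et, , drop = FALSE]
      tab <- table(factor(sub$label, levels = CLASSES))
      if (any(tab < k)) next
      r <- cv_once(sub, k, seed, ...)
      rows[[et]] <- data.frame(event_type = et, precision = r$precision,
                               recall = r$recall, f_measure = r$f_measure,
                               auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg,
                               stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) {
      per_event_df <- do.call(rbind, rows)
      rownames(per_event_df) <- NULL
    }
  }
  structure(c(rep_main, list(per_event = per_event_df)),
            class = "eval_report")
}

cv_once <- function(features, k, seed, ...) {
  labels <- as.character(features$label)
  if (anyNA(labels)) stop("evaluation requires labeled candidates")
  folds <- stratified_folds(labels, k, seed)
  fold_labels <- list(); fold_auc <- numeric(length(folds))
  for (j in seq_along(folds)) {
    test <- folds[[j]]
    train <- setdiff(seq_along(labels), test)
    model <- fit_evidence_model(features[train, , drop = FALSE], ...)
    ranked <- rank_evidence(model, features[test, , drop = FALSE])
    fold_labels[[j]] <- ranked$label
    fold_auc[j] <- auc_score(ranked$score, ranked$label)
  }
  best <- best_cutoff_f(fold_labels)
  list(precision = best$precision, recall = best$recall,
       f_measure = best$f_measure, auc = mean(fold_auc),
       cutoff_fraction = best$cutoff_fraction,
       n_pos = sum(labels == "POSITIVE"), n_neg = sum(labels == "NEGATIVE"),
       seed = seed)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> P %.1f  R %.1f  F %.1f  AUC %.1f ",
                     "(cutoff %.2f; %d pos / %d neg)\n"),
              x$precision, x$recall, x$f_measure, x$auc,
              x$cutoff_fraction, x$n_pos, x$n_neg))
  if (!is.null(x$per_event)) {
    print(x$per_event, row.names = FALSE)
  }
  invisible(x)
}

#' Single-feature ablation
#'
#' Cross-validates a model restricted to each of the ten features in turn
#' (the two dependent features keep their conditioning variable), plus the
#' all-features model, mirroring a per-feature accuracy table.
#'
#' @param features Labeled feature data.frame.
#' @param k Folds (default 5).
#' @param seed RNG seed (default 42).
#' @param ... Passed to [fit_evidence_model()].
#' @return data.frame with columns `feature`, `f_measure`, `auc` (the last
#'   row is `all`).
#' @export
single_feature_ablation <- function(features, k = 5, seed = 42, ...) {
  rows <- list()
  for (f in feature_names()) {
    r <- cv_once(features, k, seed, feature_subset = f, ...)
    rows[[f]] <- data.frame(feature = f, f_measure = r$f_measure,
                            auc = r$auc, stringsAsFactors = FALSE)
  }
  r <- cv_once(features, k, seed, ...)
  rows[["all"]] <- data.frame(feature = "all", f_measure = r$f_measure,
                              auc = r$auc, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
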