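#' Aggregate per-image probabilities to per-molecule scores
#'
#' One score per molecule: the median of its per-image probabilities
#' (for an even image count, the mean of the two central values). The
#' median over rotated views damps view-specific misclassifications and is
#' the representative molecule score used by all downstream metrics.
#'
#' @param predictions data.frame with columns `mol_id` and `probability`
#'   (one row per image).
#' @return data.frame with columns `mol_id`, `score`, `n_images`.
#' @export
aggregate_median <- function(predictions) {
  stopifnot(all(c("mol_id", "probability") %in% names(predictions)))
  if (nrow(predictions) == 0L)
    return(data.frame(mol_id = character(0), score = numeric(0),
                      n_images = integer(0), stringsAsFactors = FALSE))
  if (any(predictions$probability < 0 | predictions$probability > 1))
    stop("probabilities must lie in [0, 1]")
  sp <- split(predictions$probability, predictions$mol_id)
  data.frame(mol_id = names(sp),
             score = vapply(sp, stats::median, numeric(1L)),
             n_images = vapply(sp, length, integer(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# labels to logical actives, validating binary input
.as_active <- function(labels) {
  lab <- as.character(labels)
  ok <- lab %in% c("active", "inactive")
  if (!all(ok)) stop("labels must be 'active'/'inactive'")
  lab == "active"
}

#' ROC curve and AUC
#'
#' AUC is computed as the normalised rank statistic: the probability that
#' a randomly chosen active outscores a randomly chosen inactive, with
#' ties counted 1/2 (equivalently, the trapezoidal area under the ROC
#' curve). Curve points are `(1 - specificity, sensitivity)` at every
#' distinct threshold.
#'
#' @param scores numeric vector of molecule scores.
#' @param labels character vector (`"active"`/`"inactive"`), parallel to
#'   `scores`.
#' @return list with `auc` (number) and `curve` (data.frame `fpr`, `tpr`,
#'   `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  act <- .as_active(labels)
  n_pos <- sum(act); n_neg <- sum(!act)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[act]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    fpr = c(0, vapply(thr, function(t) sum(!act & scores >= t) / n_neg,
                      numeric(1L))),
    tpr = c(0, vapply(thr, function(t) sum(act & scores >= t) / n_pos,
                      numeric(1L))),
    threshold = c(Inf, thr))
  list(auc = auc, curve = curve)
}

#' Select a classification cutoff by the Youden index
#'
#' Scans candidate thresholds (midpoints of adjacent distinct scores,
#' plus outer sentinels) and returns the one maximising
#' `J = sensitivity + specificity - 1`. Ties are broken toward higher
#' specificity (the higher threshold). Typically run on validation-set
#' scores and then reused frozen on the test set.
#'
#' @inheritParams roc_auc
#' @return the selected threshold (score >= threshold is called active).
#' @export
select_cutoff <- function(scores, labels) {
  act <- .as_active(labels)
  if (all(act) || !any(act))
    stop("both classes must be present to select a cutoff")
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) s else
    c((s[-length(s)] + s[-1L]) / 2, s[length(s)] + 1e-6)
  best <- -Inf; best_thr <- cand[1L]
  for (t in cand) {
    pred <- scores >= t
    sens <- sum(pred & act) / sum(act)
    spec <- sum(!pred & !act) / sum(!act)
    j <- sens + spec - 1
    if (j > best || (j == best && t > best_thr)) {
      best <- j; best_thr <- t
    }
  }
  best_thr
}

#' Confusion-matrix metric suite
#'
#' Thresholds the molecule scores (`score >= threshold` is called active)
#' and computes the full metric bundle: sensitivity, specificity, balanced
#' accuracy `BAC = (sensitivity + specificity) / 2`, accuracy, precision,
#' recall, `F = 2 * recall * precision / (recall + precision)`, and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, plus the
#' rank-statistic AUC of the scores. Zero-denominator conventions:
#' precision (and F) are 0 when no positives are called; MCC is 0 when any
#' marginal is empty; such cases are flagged in `degenerate`.
#'
#' @inheritParams roc_auc
#' @param threshold finite classification cutoff (see [select_cutoff()]).
#' @return list of class `metrics_bundle` with counts, all rate metrics,
#'   `auc`, `threshold` and a `degenerate` flag.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  act <- .as_active(labels)
  pred <- scores >= threshold
  tp <- sum(pred & act); fp <- sum(pred & !act)
  tn <- sum(!pred & !act); fn <- sum(!pred & act)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  precision <- safe_div(tp, tp + fp)
  recall <- sens
  f_value <- if (precision + recall == 0) { degenerate <- TRUE; 0 } else
    2 * recall * precision / (recall + precision)
  mcc_den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) { degenerate <- TRUE; 0 } else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(mcc_den)
  auc <- if (any(act) && !all(act)) roc_auc(scores, labels)$auc else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec,
    bac = (sens + spec) / 2,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = precision, recall = recall, f_value = f_value,
    mcc = mcc, auc = auc, threshold = threshold,
    degenerate = degenerate), class = "metrics_bundle")
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d  (threshold %.4g)\n",
              x$tp, x$fp, x$tn, x$fn, x$threshold))
  for (nm in c("sensitivity", "specificity", "bac", "accuracy",
               "precision", "recall", "f_value", "mcc", "auc"))
    cat(sprintf("  %-12s %.4f\n", nm, x[[nm]]))
  if (x$degenerate) cat("  (zero-denominator convention applied)\n")
  invisible(x)
}

#' Evaluate aggregated molecule scores against labels
#'
#' Convenience wrapper: median aggregation, optional Youden cutoff
#' selection on a validation table, then the metric bundle on the test
#' table.
#'
#' @param predictions per-image prediction data.frame (`mol_id`,
#'   `probability`).
#' @param labels named vector mapping `mol_id` to `"active"/"inactive"`.
#' @param threshold classification cutoff; if `NULL`, selected on
#'   `val_predictions` (or on `predictions` when no validation table is
#'   given, flagged in the result).
#' @param val_predictions optional validation per-image predictions used
#'   for cutoff selection.
#' @return a `metrics_bundle` (see [confusion_metrics()]).
#' @export
evaluate_predictions <- function(predictions, labels, threshold = NULL,
                                 val_predictions = NULL) {
  scores <- aggregate_median(predictions)
  y <- unname(labels[scores$mol_id])
  if (anyNA(y)) stop("missing labels for some molecules")
  if (is.null(threshold)) {
    src <- if (is.null(val_predictions)) scores else
      aggregate_median(val_predictions)
    ysrc <- unname(labels[src$mol_id])
    threshold <- select_cutoff(src$score, ysrc)
  }
  confusion_metrics(scores$score, y, threshold)
}
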