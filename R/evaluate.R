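# Evaluation suite: confusion-matrix metrics, ROC/AUC, stratified
# cross-validation, validation gap, coefficient ranking.

#' Confusion matrix with AD as the positive class
#'
#' @param truth,predicted Character vectors of equal length with labels in
#'   `{positive, negative}`.
#' @param positive,negative Class labels (defaults `"AD"`/`"CN"`).
#' @return Object of class `confusion_matrix`: list with integer counts
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, predicted, positive = "AD", negative = "CN") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  ok <- c(positive, negative)
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be in {", positive, ", ", negative, "}")
  }
  structure(list(
    TP = sum(truth == positive & predicted == positive),
    TN = sum(truth == negative & predicted == negative),
    FP = sum(truth == negative & predicted == positive),
    FN = sum(truth == positive & predicted == negative),
    positive = positive, negative = negative
  ), class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param TP,TN,FP,FN Non-negative integer counts (AD positive).
#' @param positive,negative Class labels.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(TP, TN, FP, FN, positive = "AD",
                             negative = "CN") {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = as.integer(TP), TN = as.integer(TN),
                 FP = as.integer(FP), FN = as.integer(FN),
                 positive = positive, negative = negative),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L,
              dimnames = list(truth = c(x$positive, x$negative),
                              predicted = c(x$positive, x$negative)))
  print(m)
  invisible(x)
}

.safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, per-class precision, recall and F1. A metric whose
#' denominator is zero is reported as `NA` (undefined), never silently 0.
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `precision` (named by class), `recall`
#'   (named by class), `f1` (named by class), `n`, and the input counts.
#' @examples
#' metrics(confusion_counts(TP = 32, TN = 125, FP = 14, FN = 4))
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  pos <- cm$positive
  neg <- cm$negative
  precision <- c(.safe_ratio(cm$TP, cm$TP + cm$FP),
                 .safe_ratio(cm$TN, cm$TN + cm$FN))
  recall <- c(.safe_ratio(cm$TP, cm$TP + cm$FN),
              .safe_ratio(cm$TN, cm$TN + cm$FP))
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  names(precision) <- names(recall) <- names(f1) <- c(pos, neg)
  structure(list(
    accuracy = .safe_ratio(cm$TP + cm$TN, n),
    sensitivity = recall[[pos]],
    specificity = recall[[neg]],
    precision = precision, recall = recall, f1 = f1,
    n = n, counts = cm
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3L, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(round(v, digits))
  pos <- x$counts$positive
  neg <- x$counts$negative
  cat(sprintf("n = %d  (TP %d, TN %d, FP %d, FN %d; positive = %s)\n", x$n,
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN, pos))
  cat(sprintf("  accuracy %s, sensitivity %s, specificity %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity)))
  cat(sprintf("  precision: %s %s / %s %s;  F1: %s %s / %s %s\n",
              pos, fmt(x$precision[[pos]]), neg, fmt(x$precision[[neg]]),
              pos, fmt(x$f1[[pos]]), neg, fmt(x$f1[[neg]])))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct score values (plus
#' sentinels) and records (FPR, TPR); the AUC is the trapezoidal area,
#' which equals the Mann-Whitney statistic — the fraction of
#' (positive, negative) pairs ranked concordantly, ties counted 1/2.
#'
#' @param truth Character labels with both classes present.
#' @param scores Finite numeric scores (higher = more positive-like).
#' @param positive Positive class label.
#' @return Object of class `roc_curve`: data.frame-backed list with
#'   `fpr`, `tpr`, `thresholds` and scalar `auc`.
#' @export
roc_auc <- function(truth, scores, positive = "AD") {
  truth <- as.character(truth)
  stopifnot(length(truth) == length(scores), all(is.finite(scores)))
  is_pos <- truth == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[is_pos] >= t) / n_pos, numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores[!is_pos] >= t) / n_neg, numeric(1L))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d threshold(s), %d positive / %d negative, AUC = %.4f\n",
              length(x$thresholds), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  invisible(x)
}

#' Area under a ROC curve
#' @param x A `roc_curve`.
#' @return The AUC as a scalar in `[0, 1]`.
#' @export
auc <- function(x) {
  stopifnot(inherits(x, "roc_curve"))
  x$auc
}

# Stratified k-fold assignment: per class, shuffle and deal round-robin so
# fold sizes and per-fold class counts differ by at most 1.
.stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has fewer than k = %d members", cl, k))
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated AUC of the percentile classifier
#'
#' For each fold, the full no-leakage protocol is refit on the other
#' k - 1 folds — scaler, class weights and logistic coefficients — and the
#' AUC is measured on the held-out fold. Folds are class-stratified,
#' disjoint, and cover the input.
#'
#' @param percentiles Numeric matrix of raw percentile features (n x R).
#' @param diagnosis Character labels (`"AD"`/`"CN"`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param C,max_iter,tol Passed to [ad_classifier()].
#' @return Object of class `cv_result`: `fold_auc` (length k), `mean`,
#'   `sd` (k - 1 denominator), `k`, `folds` (assignment vector).
#' @export
cross_validate <- function(percentiles, diagnosis, k = 5L, seed = 42L,
                           C = 1.0, max_iter = 1000L, tol = 1e-6) {
  X <- as.matrix(percentiles)
  labels <- as.character(diagnosis)
  fold <- .stratified_folds(labels, k, seed)
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- ad_classifier(X[tr, , drop = FALSE], labels[tr], C = C,
                         max_iter = max_iter, tol = tol, seed = seed)
    prob <- predict(fit, X[!tr, , drop = FALSE])
    fold_auc[f] <- roc_auc(labels[!tr], prob)$auc
  }
  structure(list(fold_auc = fold_auc, mean = mean(fold_auc),
                 sd = stats::sd(fold_auc), k = as.integer(k),
                 folds = fold, seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV: AUC %.3f +/- %.3f  [%s]\n",
              x$k, x$mean, x$sd,
              paste(sprintf("%.3f", x$fold_auc), collapse = ", ")))
  invisible(x)
}

#' Validation gap between internal and external AUC
#'
#' `|auc_internal - auc_external|`; a gap near zero indicates the model
#' learned features that generalize across cohorts rather than
#' dataset-specific patterns.
#'
#' @param auc_internal,auc_external AUC values in `[0, 1]`.
#' @return Absolute difference.
#' @export
validation_gap <- function(auc_internal, auc_external) {
  stopifnot(auc_internal >= 0, auc_internal <= 1,
            auc_external >= 0, auc_external <= 1)
  abs(auc_internal - auc_external)
}

#' Mean validation AUC across the two independent validation sets
#'
#' @inheritParams validation_gap
#' @return `(auc_internal + auc_external) / 2`.
#' @export
mean_validation_auc <- function(auc_internal, auc_external) {
  stopifnot(auc_internal >= 0, auc_internal <= 1,
            auc_external >= 0, auc_external <= 1)
  (auc_internal + auc_external) / 2
}

#' Rank model coefficients by absolute magnitude
#'
#' Orders regions by `|beta|` descending, sign retained; ties are broken by
#' canonical region order. Because features are standardized at fit time,
#' magnitudes are directly comparable across regions.
#'
#' @param model An [ad_classifier()], or a named numeric coefficient
#'   vector.
#' @return data.frame with columns `region`, `coefficient`, ordered by
#'   decreasing `|coefficient|`.
#' @export
rank_coefficients <- function(model) {
  if (inherits(model, "ad_classifier")) {
    beta <- model$coefficients
  } else {
    beta <- model
    if (is.null(names(beta))) stop("coefficient vector must be named")
  }
  canon_pos <- match(region_key(names(beta)), region_key(brain_regions()))
  if (anyNA(canon_pos)) canon_pos <- seq_along(beta)  # non-canonical names
  ord <- order(-abs(beta), canon_pos)
  data.frame(region = names(beta)[ord],
             coefficient = unname(beta[ord]),
             stringsAsFactors = FALSE)
}
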