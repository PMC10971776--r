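# Evaluation metrics: AUC-ROC with DeLong confidence intervals,
# threshold-0.5 confusion metrics with Wilson and bootstrap intervals.

.check_two_classes <- function(labels) {
  u <- unique(labels)
  if (length(u) < 2L) {
    stop("metric undefined: both classes must be present")
  }
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability estimate P(score+ > score-) + 0.5 P(tie),
#' computed via pROC.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  .check_two_classes(labels)
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  as.numeric(pROC::auc(r))
}

#' DeLong 95% confidence interval for the AUC
#'
#' Normal-approximation interval from the DeLong structural-components
#' variance estimator, clipped to `[0, 1]`. A degenerate (zero) variance
#' collapses the interval to the point estimate with a warning.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels; at least two members per class.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  .check_two_classes(labels)
  if (min(table(labels)) < 2L) stop("need at least 2 members per class")
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong", conf.level = level)))
  lo <- max(0, min(1, ci[1])); hi <- max(0, min(1, ci[3]))
  if (isTRUE(all.equal(lo, hi)) && !(ci[2] %in% c(0, 1))) {
    warning("degenerate DeLong variance: interval collapsed to a point")
  }
  c(lower = lo, upper = hi)
}

.wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  # prop.test warns about its chi-square test at small counts; only the
  # Wilson interval is used here
  ci <- suppressWarnings(
    stats::prop.test(x, n, conf.level = level, correct = FALSE))$conf.int
  c(ci[1], ci[2])
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and F1 =
#' 2TP/(2TP+FP+FN) at the given threshold (predicted positive when score
#' >= threshold), with Wilson 95% intervals for the two proportions and a
#' seeded nonparametric bootstrap interval for F1.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @param boot_reps Bootstrap replicates for the F1 interval (default
#'   2000).
#' @param seed Bootstrap seed.
#' @return List with confusion counts, the three metrics and their 95%
#'   intervals.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5,
                                   boot_reps = 2000L, seed = 1L) {
  .check_two_classes(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  f1_boot <- .with_local_seed(seed, {
    n <- length(labels)
    vapply(seq_len(boot_reps), function(i) {
      idx <- sample.int(n, replace = TRUE)
      p <- pred[idx]; y <- labels[idx]
      tpb <- sum(p == 1L & y == 1L)
      2 * tpb / (2 * tpb + sum(p == 1L & y == 0L) + sum(p == 0L & y == 1L))
    }, 0)
  })
  list(
    confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
    sensitivity = sens, sensitivity_ci = .wilson_ci(tp, tp + fn),
    specificity = spec, specificity_ci = .wilson_ci(tn, tn + fp),
    f1 = f1,
    f1_ci = unname(stats::quantile(f1_boot, c(0.025, 0.975), na.rm = TRUE))
  )
}

#' Evaluate a trained model on a test set
#'
#' @param model A trained `mg_model`.
#' @param samples Labelled test `mg_graph` samples.
#' @param threshold Decision threshold for the confusion metrics.
#' @return List (an evaluation report): `auc`, `auc_ci` (DeLong 95%),
#'   the [classification_metrics()] fields, `n`, and the ROC curve points
#'   (`roc_fpr`, `roc_tpr`).
#' @export
evaluate_model <- function(model, samples, threshold = 0.5) {
  scores <- predict_model(model, samples)
  labels <- vapply(samples, function(s) as.numeric(s$y), 0)
  .check_two_classes(labels)
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  cm <- classification_metrics(scores, labels, threshold)
  c(list(auc = as.numeric(pROC::auc(r)),
         auc_ci = delong_ci(scores, labels),
         n = length(labels),
         roc_fpr = 1 - r$specificities,
         roc_tpr = r$sensitivities,
         scores = scores, labels = labels),
    cm)
}
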