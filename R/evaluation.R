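# Classification metrics with grade banding, Mann-Whitney AUC, and the
# Welch t comparison of group score summaries. DD is the positive class
# throughout (sensitivity = correct rate of DD, specificity = correct rate
# of TD).

#' Build a confusion matrix
#'
#' @param tp,fp,fn,tn cell counts (positive class = DD).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(TP = as.integer(tp), FP = as.integer(fp),
                 FN = as.integer(fn), TN = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP %d  FP %d\nFN %d  TN %d   (N = %d)\n",
              x$TP, x$FP, x$FN, x$TN, x$TP + x$FP + x$FN + x$TN))
  invisible(x)
}

#' @export
`+.confusion_matrix` <- function(e1, e2) {
  confusion_matrix(e1$TP + e2$TP, e1$FP + e2$FP, e1$FN + e2$FN, e1$TN + e2$TN)
}

#' Grade-banded confusion matrices
#'
#' Counts are reported separately for lower (Grades 2-3) and higher
#' (Grades 4-6) grades; the overall matrix is their cellwise sum.
#'
#' @param prob predicted DD probabilities (or 0/1 predictions).
#' @param label true status: `"DD"`/`"TD"` or 1/0.
#' @param grade integer grades in 2-6.
#' @param threshold decision threshold applied to `prob`.
#' @return A list `g23`, `g456`, `overall` of `confusion_matrix` objects.
#' @export
confusion_by_band <- function(prob, label, grade, threshold = 0.5) {
  if (length(prob) != length(label) || length(prob) != length(grade))
    stop("prob, label and grade must have equal length")
  y <- if (is.character(label) || is.factor(label))
    as.integer(as.character(label) == "DD") else as.integer(label)
  pred <- as.integer(prob >= threshold)
  one_band <- function(sel) {
    confusion_matrix(sum(pred[sel] == 1 & y[sel] == 1),
                     sum(pred[sel] == 1 & y[sel] == 0),
                     sum(pred[sel] == 0 & y[sel] == 1),
                     sum(pred[sel] == 0 & y[sel] == 0))
  }
  g23 <- one_band(grade <= 3)
  g456 <- one_band(grade >= 4)
  list(g23 = g23, g456 = g456, overall = g23 + g456)
}

#' Metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param cm a `confusion_matrix`.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`, `n`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$FP + cm$FN + cm$TN
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(accuracy = safe(cm$TP + cm$TN, n),
                 sensitivity = safe(cm$TP, cm$TP + cm$FN),
                 specificity = safe(cm$TN, cm$TN + cm$FP),
                 n = n)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  cbind(tibble::tibble(TP = x$TP, FP = x$FP, FN = x$FN, TN = x$TN),
        classification_metrics(x))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of (DD, TD) pairs in which the DD participant receives the
#' higher score; ties count one half. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores predicted probabilities or any monotone risk score.
#' @param label `"DD"`/`"TD"` or 1/0 (DD positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, label) {
  y <- if (is.character(label) || is.factor(label))
    as.integer(as.character(label) == "DD") else as.integer(label)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Welch's t test from group summaries
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, computed from (N, mean, SD) summaries.
#'
#' @param n1,m1,s1 size, mean, SD of group 1.
#' @param n2,m2,s2 size, mean, SD of group 2.
#' @return A one-row tibble: `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t, df = df,
                 p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Group comparison of dictation scores per grade
#'
#' Welch's t for TD vs DD mean number-correct within each grade, computed
#' from a summary table shaped like [dictation_norms()].
#'
#' @param norms tibble with `grade`, `status`, `n`, `mean_correct`,
#'   `sd_correct`.
#' @return A tibble with one row per grade: `grade`, `t`, `df`, `p`.
#' @export
group_comparison <- function(norms = dictation_norms()) {
  purrr::map_dfr(sort(unique(norms$grade)), function(g) {
    td <- norms[norms$grade == g & norms$status == "TD", ]
    dd <- norms[norms$grade == g & norms$status == "DD", ]
    cbind(tibble::tibble(grade = g),
          welch_t(td$n, td$mean_correct, td$sd_correct,
                  dd$n, dd$mean_correct, dd$sd_correct))
  })
}

#' Published ablation reference results
#'
#' Band confusion matrices (TP, FP, FN, TN for Grades 2-3 and 4-6) and the
#' printed overall metrics for the 16 DysDiTect variants on the original
#' study's held-out test set (N = 107), as distributed with the package.
#'
#' @return A tibble with one row per variant.
#' @export
reference_ablation <- function() {
  path <- system.file("extdata", "reference_ablation.csv",
                      package = "dysditect", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Evaluate a fitted model on one partition
#'
#' @param fit a `dysditect_fit` (or `dysditect_model`).
#' @param cohort a rendered `dictation_cohort`.
#' @param split a split tibble from [stratified_split()].
#' @param partition which partition to evaluate.
#' @param threshold decision threshold.
#' @return A list: `predictions` (tibble), `confusion` (band list), and
#'   `metrics` (one-row tibble with accuracy, sensitivity, specificity,
#'   `auc`, and the band confusion cells).
#' @export
evaluate_fit <- function(fit, cohort, split, partition = "test",
                         threshold = 0.5) {
  ids <- split$participant_id[split$partition == partition]
  preds <- predict_participants(fit, cohort, ids, threshold = threshold)
  cms <- confusion_by_band(preds$prob, preds$status, preds$grade, threshold)
  metrics <- classification_metrics(cms$overall)
  metrics$auc <- auc_mann_whitney(preds$prob, preds$status)
  band_cells <- tibble::tibble(
    tp_g23 = cms$g23$TP, fp_g23 = cms$g23$FP,
    fn_g23 = cms$g23$FN, tn_g23 = cms$g23$TN,
    tp_g456 = cms$g456$TP, fp_g456 = cms$g456$FP,
    fn_g456 = cms$g456$FN, tn_g456 = cms$g456$TN)
  list(predictions = preds, confusion = cms,
       metrics = cbind(metrics, band_cells))
}
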