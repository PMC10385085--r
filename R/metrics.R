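#' Build a 3x3 confusion matrix
#'
#' Rows are true affect classes, columns predicted, both in the canonical
#' order negative, positive, neutral.
#'
#' @param truth,predicted Factors or characters over [affect_states()].
#' @return Integer matrix with class `table`.
#' @export
confusion_matrix <- function(truth, predicted) {
  table(truth = as_affect_factor(as.character(truth)),
        predicted = as_affect_factor(as.character(predicted)))
}

#' Classification accuracy from a confusion matrix
#'
#' The fraction of windows whose predicted class equals the true class —
#' the trace of the confusion matrix over its total, which coincides with
#' the micro-averaged one-vs-rest accuracy `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param conf Square confusion matrix (true x predicted).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' accuracy(matrix(c(5, 0, 0, 5, 10, 0, 0, 0, 10), nrow = 3))
accuracy <- function(conf) {
  conf <- as.matrix(conf)
  total <- sum(conf)
  if (total <= 0) abort("Confusion matrix is empty.")
  sum(diag(conf)) / total
}

#' Macro-averaged precision, recall and F1
#'
#' Per-class precision (column-wise) and recall (row-wise) are averaged over
#' the three classes; a class never predicted (or absent from the truth)
#' contributes 0 to the average. F1 is the harmonic mean of macro precision
#' and macro recall.
#'
#' @param conf Square confusion matrix (true x predicted).
#' @return Named list: `precision`, `recall`, `f1`.
#' @export
macro_prf <- function(conf) {
  conf <- as.matrix(conf)
  if (sum(conf) <= 0) abort("Confusion matrix is empty.")
  tp <- diag(conf)
  col_tot <- colSums(conf)
  row_tot <- rowSums(conf)
  precision <- ifelse(col_tot > 0, tp / col_tot, 0)
  recall <- ifelse(row_tot > 0, tp / row_tot, 0)
  mp <- mean(precision)
  mr <- mean(recall)
  f1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  list(precision = mp, recall = mr, f1 = f1)
}
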