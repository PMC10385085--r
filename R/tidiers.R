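#' Tidy a cross-validation result
#'
#' One row per fold with its held-out accuracy and size.
#'
#' @param x An `affect_cv` object from [kfold_cv()].
#' @param ... Unused.
#' @return Tibble with columns `fold`, `n`, `accuracy`.
#' @method tidy affect_cv
#' @export
tidy.affect_cv <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$k),
                 n = x$fold_sizes,
                 accuracy = x$per_fold_accuracy)
}

#' One-row summary of a cross-validation result
#'
#' @param x An `affect_cv` object from [kfold_cv()].
#' @param ... Unused.
#' @return One-row tibble: classifier, k, n, mean accuracy, macro
#'   precision/recall/F1.
#' @method glance affect_cv
#' @export
glance.affect_cv <- function(x, ...) {
  tibble::tibble(classifier = x$classifier,
                 k = x$k,
                 n = x$n,
                 mean_accuracy = x$mean_accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 f1 = x$f1)
}
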