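#' Build evaluation datasets from a cohort feature table
#'
#' In the subject-dependent (`intra_subject`) protocol each subject's windows
#' form their own dataset — the classifier is trained and tested within one
#' individual. In the subject-independent (`inter_subject`) protocol all
#' subjects' windows are pooled into a single dataset.
#'
#' @param features Feature tibble from [assemble_features()] with a
#'   `subject_id` column.
#' @param mode `"intra_subject"` or `"inter_subject"`.
#' @param min_windows Minimum windows a dataset needs (default 10, one per
#'   cross-validation fold).
#'
#' @return Tibble with columns `dataset_id`, `mode`, `subject_scope` and
#'   list-column `data` (one feature tibble per dataset).
#' @export
build_dataset <- function(features, mode = c("intra_subject",
                                             "inter_subject"),
                          min_windows = 10) {
  mode <- match.arg(mode)
  if (!"subject_id" %in% names(features)) {
    abort("`features` must have a `subject_id` column.")
  }
  groups <- if (mode == "intra_subject") {
    split(features, features$subject_id)
  } else {
    list(pooled = features)
  }
  purrr::imap(groups, function(d, id) {
    if (nrow(d) < min_windows) {
      abort(sprintf(
        "Dataset `%s` has %d windows; %d-fold CV needs at least %d. Use a smaller k.",
        id, nrow(d), min_windows, min_windows))
    }
    n_classes <- length(unique(as.character(d$affect)))
    if (n_classes < 2L) {
      abort(sprintf("Dataset `%s` contains a single class; cannot train.", id))
    }
    tibble::tibble(dataset_id = id, mode = mode,
                   subject_scope = if (mode == "intra_subject") id else
                     paste(unique(d$subject_id), collapse = ","),
                   data = list(d))
  }) |>
    dplyr::bind_rows()
}

feature_matrix <- function(data) {
  cols <- grep("^f[0-9]+$", names(data), value = TRUE)
  as.matrix(data[cols])
}

# Stratified fold assignment: within each class, windows are shuffled and
# dealt round-robin into k folds. The dealing position carries over from one
# class to the next, so overall fold sizes differ by at most one while every
# fold mirrors the class balance.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

fit_predict <- function(classifier, x_train, y_train, x_test, seed) {
  y_train <- droplevels(factor(y_train, levels = affect_states()))
  pred <- switch(classifier,
    svm = {
      fit <- e1071::svm(x_train, y_train, kernel = "radial", cost = 1,
                        scale = FALSE)
      predict(fit, x_test)
    },
    knn = with_seed(seed, class::knn(x_train, x_test, y_train, k = 5)),
    random_forest = {
      fit <- with_seed(seed,
                       randomForest::randomForest(x_train, y_train,
                                                  ntree = 100))
      predict(fit, x_test)
    },
    abort(sprintf("Unknown classifier `%s`.", classifier))
  )
  as.character(pred)
}

#' Stratified k-fold cross-validation of an affect classifier
#'
#' Partitions the dataset into `k` stratified folds, then for each fold fits
#' the classifier on the remaining `k - 1` folds and predicts the held-out
#' windows. Features are z-scored using training-fold statistics only, so no
#' information leaks from the test fold. The confusion matrix is pooled over
#' folds.
#'
#' Classifiers follow standard defaults: RBF-kernel SVM with cost 1, 5-nearest
#' neighbours (Euclidean), and a 100-tree random forest with Gini splitting.
#'
#' @param data One dataset tibble (a row of [build_dataset()]'s `data`
#'   list-column): feature columns `f1..fk` plus `affect`.
#' @param classifier `"svm"`, `"knn"` or `"random_forest"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and any classifier
#'   randomness.
#'
#' @return Object of class `affect_cv` with per-fold accuracies, the pooled
#'   confusion matrix, macro precision/recall/F1 and run metadata. Use
#'   [tidy()] for per-fold rows and [glance()] for a one-row summary.
#' @export
kfold_cv <- function(data, classifier = c("svm", "knn", "random_forest"),
                     k = 10, seed = 1L) {
  classifier <- match.arg(classifier)
  check_number(k, "k", 2)
  if (nrow(data) < k) {
    abort(sprintf("Dataset has %d windows; %d-fold CV needs at least %d.",
                  nrow(data), k, k))
  }
  labels <- as.character(data$affect)
  x <- feature_matrix(data)
  seeds <- derive_seeds(seed, k + 2L)
  fold <- stratified_folds(labels, k, seeds[1])
  # A class can still miss a training split in pathological class balances:
  # re-draw once, then fail loudly.
  check_folds <- function(fold) {
    all(purrr::map_lgl(seq_len(k), function(f) {
      length(unique(labels[fold != f])) >= 2L && sum(fold == f) > 0L
    }))
  }
  if (!check_folds(fold)) {
    fold <- stratified_folds(labels, k, seeds[2])
    if (!check_folds(fold)) {
      abort("A class is absent from a training split even after a re-draw.")
    }
  }
  per_fold <- purrr::map(seq_len(k), function(f) {
    train <- fold != f
    mu <- colMeans(x[train, , drop = FALSE])
    sdv <- apply(x[train, , drop = FALSE], 2, sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    x_train <- sweep(sweep(x[train, , drop = FALSE], 2, mu), 2, sdv, "/")
    x_test <- sweep(sweep(x[!train, , drop = FALSE], 2, mu), 2, sdv, "/")
    pred <- fit_predict(classifier, x_train, labels[train], x_test,
                        seeds[f + 2L])
    truth <- labels[!train]
    list(accuracy = mean(pred == truth),
         truth = truth, pred = pred, n = length(truth))
  })
  truth_all <- unlist(purrr::map(per_fold, "truth"))
  pred_all <- unlist(purrr::map(per_fold, "pred"))
  conf <- confusion_matrix(truth_all, pred_all)
  prf <- macro_prf(conf)
  structure(
    list(per_fold_accuracy = purrr::map_dbl(per_fold, "accuracy"),
         fold_sizes = purrr::map_int(per_fold, "n"),
         mean_accuracy = mean(purrr::map_dbl(per_fold, "accuracy")),
         confusion = conf,
         macro_precision = prf$precision,
         macro_recall = prf$recall,
         f1 = prf$f1,
         classifier = classifier,
         k = as.integer(k),
         n = nrow(data),
         seed = as.integer(seed)),
    class = "affect_cv"
  )
}

#' @export
print.affect_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV, %s, n = %d\n", x$k, x$classifier, x$n))
  cat(sprintf("  mean accuracy : %.3f\n", x$mean_accuracy))
  cat(sprintf("  macro P/R/F1  : %.3f / %.3f / %.3f\n",
              x$macro_precision, x$macro_recall, x$f1))
  cat("  confusion (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate classifiers across datasets
#'
#' Runs [kfold_cv()] for every combination of dataset and classifier and
#' collects the results in one tidy table.
#'
#' @param datasets Tibble from [build_dataset()].
#' @param classifiers Character vector of classifier names.
#' @param k,seed Passed to [kfold_cv()].
#'
#' @return Tibble with one row per (dataset, classifier): identifier columns,
#'   summary metrics, and the `affect_cv` objects in a `cv` list-column.
#' @export
evaluate_datasets <- function(datasets,
                              classifiers = c("svm", "knn", "random_forest"),
                              k = 10, seed = 1L) {
  grid <- tidyr::expand_grid(i = seq_len(nrow(datasets)),
                             classifier = classifiers)
  purrr::map2(grid$i, grid$classifier, function(i, clf) {
    cv <- kfold_cv(datasets$data[[i]], classifier = clf, k = k, seed = seed)
    dplyr::bind_cols(datasets[i, c("dataset_id", "mode")],
                     glance(cv),
                     tibble::tibble(cv = list(cv)))
  }) |>
    dplyr::bind_rows()
}

#' Compare feature schemes, window sizes and classifiers on one cohort
#'
#' The full experimental grid: for each window length the cohort is
#' re-annotated (clip length changes with the window), then each feature
#' scheme is extracted and each classifier evaluated under k-fold CV in the
#' requested mode(s). This reproduces the design of the study's
#' scheme-by-classifier accuracy tables.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param window_s Window lengths in seconds (default `c(2, 3, 5)`).
#' @param schemes Feature schemes (default both).
#' @param classifiers Classifier names (default all three).
#' @param modes Evaluation protocols (default both).
#' @param fps,threshold,sampling_rate_hz Annotation settings (see
#'   [annotate_cohort()]).
#' @param k,seed Cross-validation settings.
#'
#' @return Tidy tibble: one row per (window_s, scheme, mode, dataset,
#'   classifier) with summary metrics and `affect_cv` objects in `cv`.
#' @export
compare_schemes <- function(cohort, window_s = c(2, 3, 5),
                            schemes = c("raw_hr", "dwt"),
                            classifiers = c("svm", "knn", "random_forest"),
                            modes = c("inter_subject", "intra_subject"),
                            fps = 25, threshold = 0.5, sampling_rate_hz = 1,
                            k = 10, seed = 1L) {
  purrr::map(window_s, function(w) {
    labeled <- annotate_cohort(cohort, fps = fps, window_s = w,
                               threshold = threshold,
                               sampling_rate_hz = sampling_rate_hz)
    purrr::map(schemes, function(sc) {
      feats <- assemble_features(labeled, scheme = sc)
      purrr::map(modes, function(m) {
        datasets <- build_dataset(feats, mode = m, min_windows = k)
        evaluate_datasets(datasets, classifiers = classifiers, k = k,
                          seed = seed) |>
          dplyr::mutate(window_s = w, scheme = sc, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
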