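#' Plot a cohort's heart-rate traces coloured by latent state
#'
#' One panel per subject; points are heart-rate samples, coloured by the
#' ground-truth affect state of the second they fall in.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @return A ggplot object.
#' @export
plot_cohort_hr <- function(cohort) {
  df <- purrr::pmap(list(cohort$subject_id, cohort$hr, cohort$truth),
                    function(id, hr, truth) {
                      sec <- pmin(floor(hr$t_s), max(truth$t_s)) + 1L
                      dplyr::mutate(hr, subject_id = id,
                                    state = truth$state[sec])
                    }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$bpm,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$subject_id), scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "heart rate (BPM)",
                  colour = "affect state") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for a cross-validation result
#'
#' @param object An `affect_cv` object from [kfold_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot affect_cv
#' @export
autoplot.affect_cv <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("%s, %d-fold CV, mean accuracy %.3f",
                                  object$classifier, object$k,
                                  object$mean_accuracy),
                  x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of accuracies across an evaluation grid
#'
#' Mirrors the per-participant accuracy figures of subject-dependent studies:
#' one bar per dataset and classifier, faceted by feature scheme when present.
#'
#' @param results Tibble from [evaluate_datasets()] or [compare_schemes()].
#' @return A ggplot object.
#' @export
plot_accuracy_grid <- function(results) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$dataset_id,
                                    y = .data$mean_accuracy,
                                    fill = .data$classifier)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean 10-fold accuracy") +
    ggplot2::theme_minimal()
  if ("scheme" %in% names(results)) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$scheme),
      cols = if ("window_s" %in% names(results))
        ggplot2::vars(.data$window_s) else NULL)
  }
  p
}
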