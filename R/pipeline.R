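#' Full-run configuration
#'
#' Bundles all stage settings of a pipeline run: the cohort generator config,
#' the annotation window and escalation threshold, the feature scheme and the
#' evaluation protocol. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param cohort A [cohort_config()].
#' @param window_s Window length in seconds (default 2; 2, 3 and 5 are the
#'   studied values).
#' @param threshold Escalation threshold (default 0.5).
#' @param scheme Feature scheme(s) to evaluate (default both).
#' @param levels DWT depth, `NULL` for maximal.
#' @param classifiers Classifier names (default all three).
#' @param modes Evaluation protocol(s) (default both).
#' @param k Cross-validation folds (default 10).
#' @param seed Master seed (defaults to the cohort seed).
#'
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       window_s = 2,
                       threshold = 0.5,
                       scheme = c("raw_hr", "dwt"),
                       levels = NULL,
                       classifiers = c("svm", "knn", "random_forest"),
                       modes = c("inter_subject", "intra_subject"),
                       k = 10,
                       seed = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  nf <- cohort$fps * window_s
  if (abs(nf - round(nf)) > 1e-9) {
    abort("`window_s * fps` must be a whole number of frames.")
  }
  n <- window_s * cohort$sampling_rate_hz
  if (n < 1) abort("`window_s * sampling_rate_hz` must be >= 1.")
  check_probability(threshold, "threshold")
  structure(
    list(cohort = cohort, window_s = window_s, threshold = threshold,
         scheme = scheme, levels = levels, classifiers = classifiers,
         modes = modes, k = k,
         seed = as.integer(if (is.null(seed)) cohort$seed else seed)),
    class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$cohort <- unclass(lst$cohort)
  lst$cohort$state_offsets <- as.list(lst$cohort$state_offsets)
  lst$cohort$state_probs <- as.list(lst$cohort$state_probs)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cc <- lst$cohort
  cohort <- cohort_config(
    n_subjects = cc$n_subjects,
    duration_range_s = unlist(cc$duration_range_s),
    baseline_bpm_mean = cc$baseline_bpm_mean,
    baseline_bpm_sd = cc$baseline_bpm_sd,
    state_offsets = unlist(cc$state_offsets),
    hr_noise_sd = cc$hr_noise_sd,
    sampling_rate_hz = cc$sampling_rate_hz,
    fps = cc$fps,
    fer_accuracy = cc$fer_accuracy,
    confidence_params = lapply(cc$confidence_params, unlist),
    dwell_mean_s = cc$dwell_mean_s,
    state_probs = unlist(cc$state_probs),
    seed = cc$seed)
  run_config(cohort = cohort, window_s = lst$window_s,
             threshold = lst$threshold, scheme = unlist(lst$scheme),
             levels = lst$levels, classifiers = unlist(lst$classifiers),
             modes = unlist(lst$modes), k = lst$k, seed = lst$seed)
}

#' Run the whole pipeline: simulate, annotate, featurize, evaluate
#'
#' Executes the four stages in order, writing every intermediate to
#' `out_dir`: the cohort CSVs, per-subject window labels and an annotation
#' audit log, per-scheme feature tables, per-combination evaluation reports
#' (JSON) and a run manifest with MD5 digests of every file. Identical
#' configurations produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(package_version = as.character(utils::packageVersion("affecthr")),
                   seed = config$seed,
                   nf = as.integer(round(config$cohort$fps * config$window_s)),
                   stages = list())
  res <- tryCatch({
    cohort <- generate_cohort(config$cohort)
    cohort_dir <- file.path(out_dir, "cohort")
    write_cohort(cohort, cohort_dir, config$cohort)
    manifest$stages$simulate <- list(dir = "cohort")

    stage <- "annotate"
    labeled <- annotate_cohort(cohort, fps = config$cohort$fps,
                               window_s = config$window_s,
                               threshold = config$threshold,
                               sampling_rate_hz = config$cohort$sampling_rate_hz)
    labels_path <- file.path(out_dir, "labels.csv")
    audit <- labeled |>
      dplyr::select(!"hr_vector")
    write.csv(audit, labels_path, row.names = FALSE)
    manifest$stages$annotate <- list(
      file = "labels.csv",
      escalation_rate = mean(labeled$provenance == "human"))

    stage <- "featurize"
    feature_files <- list()
    feats_by_scheme <- list()
    for (sc in config$scheme) {
      feats <- assemble_features(labeled, scheme = sc, levels = config$levels)
      fp <- file.path(out_dir, sprintf("features_%s.csv", sc))
      write.csv(feats |> dplyr::select(!dplyr::any_of("hr_vector")), fp,
                row.names = FALSE)
      feature_files[[sc]] <- basename(fp)
      feats_by_scheme[[sc]] <- feats
    }
    manifest$stages$featurize <- list(files = feature_files)

    stage <- "evaluate"
    reports <- purrr::map(config$scheme, function(sc) {
      purrr::map(config$modes, function(m) {
        datasets <- build_dataset(feats_by_scheme[[sc]], mode = m,
                                  min_windows = config$k)
        evaluate_datasets(datasets, classifiers = config$classifiers,
                          k = config$k, seed = config$seed) |>
          dplyr::mutate(scheme = sc, window_s = config$window_s, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    report_path <- file.path(out_dir, "evaluation.json")
    report_json <- reports |>
      dplyr::mutate(confusion = purrr::map(.data$cv,
                                           ~ unclass(as.matrix(.x$confusion))),
                    per_fold_accuracy = purrr::map(.data$cv,
                                                   "per_fold_accuracy")) |>
      dplyr::select(!"cv")
    jsonlite::write_json(report_json, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    summary_path <- file.path(out_dir, "summary.csv")
    write.csv(reports |> dplyr::select(!"cv"), summary_path,
              row.names = FALSE)
    manifest$stages$evaluate <- list(report = "evaluation.json",
                                     summary = "summary.csv")
    list(cohort = cohort, labeled = labeled, reports = reports)
  }, error = function(e) {
    abort(sprintf("Pipeline failed at stage `%s`: %s", stage,
                  conditionMessage(e)))
  })

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest$digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, res))
}

#' Render a human-readable summary of a pipeline run
#'
#' Produces a markdown report from a run directory: cohort heart-rate summary
#' (mean/min/max BPM recomputed from the written CSVs), the escalation rate,
#' and mean-accuracy tables shaped scheme x classifier for each evaluation
#' mode.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param path Optional file to write the markdown to.
#'
#' @return The report as a character vector of lines (invisibly if `path` is
#'   given).
#' @export
render_report <- function(out_dir, path = NULL) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort("`run_pipeline` manifest not found; run the pipeline first.")
  }
  manifest <- jsonlite::read_json(manifest_path)
  eval_path <- file.path(out_dir, "evaluation.json")
  if (!file.exists(eval_path)) {
    abort("Missing output of stage `evaluate` (evaluation.json).")
  }
  hr_files <- list.files(file.path(out_dir, "cohort"),
                         pattern = "^hr_.*\\.csv$", full.names = TRUE)
  if (!length(hr_files)) {
    abort("Missing output of stage `simulate` (cohort hr CSVs).")
  }
  bpm <- unlist(purrr::map(hr_files, function(f) read.csv(f)$bpm))
  reports <- jsonlite::fromJSON(eval_path)
  lines <- c(
    "# Pipeline run report", "",
    sprintf("- package version: %s", manifest$package_version),
    sprintf("- seed: %d", manifest$seed),
    sprintf("- clip length nf: %d frames", manifest$nf),
    sprintf("- escalation rate: %.3f",
            manifest$stages$annotate$escalation_rate), "",
    "## Cohort heart-rate summary", "",
    sprintf("- mean BPM: %.1f", mean(bpm)),
    sprintf("- min BPM: %.1f", min(bpm)),
    sprintf("- max BPM: %.1f", max(bpm)), "")
  for (m in unique(reports$mode)) {
    sub <- reports[reports$mode == m, ]
    agg <- stats::aggregate(mean_accuracy ~ scheme + classifier, data = sub,
                            FUN = mean)
    wide <- stats::reshape(agg, idvar = "scheme", timevar = "classifier",
                           direction = "wide")
    names(wide) <- sub("^mean_accuracy\\.", "", names(wide))
    lines <- c(lines, sprintf("## Mean accuracy, %s", m), "",
               paste(capture_table(wide), collapse = "\n"), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

capture_table <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}
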