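#' Segment a frame-prediction stream into fixed-length clips
#'
#' Divides the stream into consecutive non-overlapping clips of
#' `nf = fps * window_s` frames. A trailing remainder shorter than `nf` is
#' discarded, so the clip count is `floor(n_frames / nf)`. At 25 fps with a
#' two-second window, `nf = 50`.
#'
#' @param predictions Frame-prediction tibble (`frame_index`, `label`,
#'   `confidence`), frame indices strictly increasing from 0.
#' @param fps Video frame rate, frames per second.
#' @param window_s Clip length in seconds; `fps * window_s` must be a whole
#'   number >= 1.
#'
#' @return The input rows that fall in a complete clip, with added columns
#'   `clip_index` (0-based) and `start_time_s`.
#' @export
#' @examples
#' seq4 <- generate_state_sequence(4, state_probs = c(0, 1, 0))
#' fer <- generate_fer_stream(seq4, fps = 25, fer_accuracy = 1, seed = 1)
#' dplyr::count(segment_clips(fer, fps = 25, window_s = 2), clip_index)
segment_clips <- function(predictions, fps, window_s) {
  nf <- fps * window_s
  if (abs(nf - round(nf)) > 1e-9 || round(nf) < 1) {
    abort("`fps * window_s` must be a whole number of frames >= 1.")
  }
  nf <- as.integer(round(nf))
  if (nrow(predictions) == 0L) abort("`predictions` is empty.")
  n_clips <- nrow(predictions) %/% nf
  predictions |>
    head(n_clips * nf) |>
    dplyr::mutate(clip_index = (dplyr::row_number() - 1L) %/% nf,
                  start_time_s = .data$clip_index * window_s)
}

#' Select the representative frame of each clip
#'
#' A clip is summarized by one frame chosen by two criteria: its label must be
#' the most frequent label in the clip, and among frames carrying that label
#' its prediction confidence must be the highest. Ties — both tied modal
#' labels and equal confidences — are broken toward the lowest frame index,
#' which makes the choice deterministic and order-stable.
#'
#' @param clips Output of [segment_clips()] (must contain `clip_index`).
#'
#' @return One row per clip: `clip_index`, `frame_index`, `fine_label`,
#'   `confidence`.
#' @export
select_representative <- function(clips) {
  if (nrow(clips) == 0L) abort("`clips` is empty.")
  clips |>
    dplyr::group_by(.data$clip_index) |>
    dplyr::add_count(.data$label, name = ".label_count") |>
    dplyr::arrange(dplyr::desc(.data$.label_count),
                   dplyr::desc(.data$confidence),
                   .data$frame_index,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(clip_index = .data$clip_index,
                     frame_index = .data$frame_index,
                     fine_label = .data$label,
                     confidence = .data$confidence)
}

#' Map a fine emotion label to its affect class
#'
#' Fear, anger, sadness and disgust are negative; happiness is positive;
#' neutral is neutral. Surprise and contempt are not covered by that rule, so
#' their targets are configurable; the defaults (surprise -> positive,
#' contempt -> negative) come from [default_affect_map()].
#'
#' @param fine Character or factor vector of fine emotion labels.
#' @param extension Named character overriding the mapping for `surprise`
#'   and/or `contempt`.
#'
#' @return Factor over [affect_states()], same length as `fine`.
#' @export
#' @examples
#' map_to_affect(c("fear", "happiness", "surprise"))
map_to_affect <- function(fine, extension = NULL) {
  map <- default_affect_map()
  if (!is.null(extension)) {
    bad <- setdiff(names(extension), c("surprise", "contempt"))
    if (length(bad)) {
      abort("`extension` may only remap `surprise` and `contempt`.")
    }
    if (!all(extension %in% affect_states())) {
      abort("`extension` values must be affect states.")
    }
    map[names(extension)] <- extension
  }
  fine <- as.character(fine)
  unknown <- setdiff(unique(fine), names(map))
  if (length(unknown)) {
    abort(paste0("Unknown fine emotion label(s): ",
                 paste(unknown, collapse = ", ")))
  }
  as_affect_factor(unname(map[fine]))
}

#' Build a human-annotator oracle backed by a ground-truth state sequence
#'
#' The human annotator is modeled as a function from a representative frame to
#' an affect state. For synthetic sessions the annotator — who watches the
#' whole clip in context — is emulated by the modal ground-truth state over
#' the clip's time span.
#'
#' @param truth State-sequence tibble (`t_s`, `state`).
#' @param window_s Clip length in seconds.
#'
#' @return A function `(rep_frame, context)` returning an affect state.
#' @export
truth_oracle <- function(truth, window_s) {
  force(truth); force(window_s)
  function(rep_frame, context = NULL) {
    t0 <- rep_frame$clip_index * window_s
    span <- truth$state[truth$t_s >= t0 & truth$t_s < t0 + window_s]
    if (!length(span)) return(as_affect_factor("neutral"))
    tab <- table(span)
    as_affect_factor(names(tab)[which.max(tab)])
  }
}

#' Decide each clip's affect label, escalating low-confidence clips
#'
#' Clips whose representative-frame confidence is at or above `threshold`
#' are labeled automatically via [map_to_affect()]; clips strictly below the
#' threshold are escalated to the human oracle. With `threshold = 0` nothing
#' is escalated; with `threshold = 1` every clip with confidence below 1 is.
#'
#' @param reps Representative-frame tibble from [select_representative()].
#' @param threshold Escalation threshold in \[0, 1\] (default 0.5).
#' @param oracle Human-annotator function `(rep_frame, context) -> state`;
#'   required whenever any clip falls below the threshold.
#' @param extension Passed to [map_to_affect()].
#'
#' @return Tibble `clip_index`, `affect`, `provenance` (`auto`/`human`),
#'   `confidence`, `escalated`.
#' @export
decide_escalation <- function(reps, threshold = 0.5, oracle = NULL,
                              extension = NULL) {
  check_probability(threshold, "threshold")
  escalated <- reps$confidence < threshold
  if (any(escalated) && is.null(oracle)) {
    abort("Clips fall below the threshold but no `oracle` was supplied.")
  }
  affect <- map_to_affect(reps$fine_label, extension)
  if (any(escalated)) {
    human <- purrr::map_chr(which(escalated), function(i) {
      res <- tryCatch(oracle(reps[i, ], NULL), error = function(e) {
        abort(sprintf("Human oracle failed on clip %d: %s",
                      reps$clip_index[i], conditionMessage(e)))
      })
      as.character(res)
    })
    if (!all(human %in% affect_states())) {
      abort("Human oracle returned a value outside the affect states.")
    }
    affect[escalated] <- human
  }
  tibble::tibble(clip_index = reps$clip_index,
                 affect = as_affect_factor(affect),
                 provenance = factor(ifelse(escalated, "human", "auto"),
                                     levels = c("auto", "human")),
                 confidence = reps$confidence,
                 escalated = escalated)
}

#' Attach clip labels to the aligned heart-rate windows
#'
#' Because heart rate and video are recorded on a shared clock, window `k` of
#' the heart-rate stream receives the label of clip `k`. Window `k` holds the
#' samples with index in `[k * n, (k + 1) * n)` where
#' `n = window_s * sampling_rate_hz`; the output length is
#' `min(n_clips, floor(n_samples / n))` — whichever stream is shorter limits
#' the labeled data. `offset_s` shifts the heart-rate indexing when the two
#' streams do not start together.
#'
#' @param hr Heart-rate tibble (`t_s`, `bpm`).
#' @param clip_labels Tibble from [decide_escalation()].
#' @param window_s Window length in seconds (matching the clip length).
#' @param sampling_rate_hz Heart-rate sampling rate (default 1).
#' @param offset_s Shift applied to the heart-rate stream start (default 0).
#'
#' @return Tibble of labeled windows: `window_index`, `affect`, `provenance`,
#'   `confidence`, and list-column `hr_vector` of length-`n` numeric vectors.
#' @export
synchronize <- function(hr, clip_labels, window_s, sampling_rate_hz = 1,
                        offset_s = 0) {
  n <- window_s * sampling_rate_hz
  if (abs(n - round(n)) > 1e-9 || round(n) < 1) {
    abort("`window_s * sampling_rate_hz` must be a whole number >= 1.")
  }
  n <- as.integer(round(n))
  bpm <- hr$bpm
  if (offset_s != 0) {
    skip <- as.integer(round(offset_s * sampling_rate_hz))
    bpm <- bpm[(skip + 1L):length(bpm)]
  }
  n_windows <- min(nrow(clip_labels), length(bpm) %/% n)
  if (n_windows < 1L) abort("No overlapping windows between HR and video.")
  labels <- clip_labels[seq_len(n_windows), ]
  tibble::tibble(
    window_index = labels$clip_index,
    affect = labels$affect,
    provenance = labels$provenance,
    confidence = labels$confidence,
    hr_vector = purrr::map(seq_len(n_windows) - 1L,
                           function(k) bpm[(k * n + 1L):((k + 1L) * n)])
  )
}

#' Annotate one session end to end
#'
#' Runs clip segmentation, representative-frame selection, confidence-based
#' escalation and heart-rate/video synchronization for a single session.
#'
#' @param hr,fer Heart-rate and frame-prediction tibbles for the session.
#' @param fps Frame rate of the prediction stream.
#' @param window_s Window length in seconds.
#' @param threshold Escalation threshold (default 0.5).
#' @param oracle Human-annotator function (see [truth_oracle()]).
#' @param sampling_rate_hz Heart-rate sampling rate (default 1).
#' @param extension Surprise/contempt mapping override.
#' @param offset_s Heart-rate start offset in seconds.
#'
#' @return Labeled-window tibble (see [synchronize()]).
#' @export
annotate_session <- function(hr, fer, fps, window_s, threshold = 0.5,
                             oracle = NULL, sampling_rate_hz = 1,
                             extension = NULL, offset_s = 0) {
  fer |>
    segment_clips(fps = fps, window_s = window_s) |>
    select_representative() |>
    decide_escalation(threshold = threshold, oracle = oracle,
                      extension = extension) |>
    synchronize(hr = hr, window_s = window_s,
                sampling_rate_hz = sampling_rate_hz, offset_s = offset_s)
}

#' Annotate every session of a cohort
#'
#' Applies [annotate_session()] per subject; when `use_truth_oracle` is `TRUE`
#' the subject's ground-truth state sequence emulates the human annotator.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param fps,window_s,threshold,sampling_rate_hz,extension See
#'   [annotate_session()].
#' @param use_truth_oracle Back escalation with the `truth` list-column
#'   (default `TRUE`).
#'
#' @return Long tibble of labeled windows with a `subject_id` column.
#' @export
annotate_cohort <- function(cohort, fps = 25, window_s = 2, threshold = 0.5,
                            sampling_rate_hz = 1, extension = NULL,
                            use_truth_oracle = TRUE) {
  purrr::map2(seq_len(nrow(cohort)), cohort$subject_id, function(i, id) {
    oracle <- if (use_truth_oracle) {
      truth_oracle(cohort$truth[[i]], window_s)
    }
    annotate_session(cohort$hr[[i]], cohort$fer[[i]], fps = fps,
                     window_s = window_s, threshold = threshold,
                     oracle = oracle, sampling_rate_hz = sampling_rate_hz,
                     extension = extension) |>
      dplyr::mutate(subject_id = id, .before = 1)
  }) |>
    dplyr::bind_rows()
}
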