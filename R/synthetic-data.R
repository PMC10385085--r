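#' Cohort generator configuration
#'
#' Bundles every parameter of the synthetic cohort generator. The defaults
#' emulate the study conditions the pipeline was designed for: nine children,
#' session durations between 480 and 846 seconds, a cohort-average heart rate
#' near 96.8 BPM, and a frame-level expression recognizer of moderate
#' accuracy running at 25 fps.
#'
#' @param n_subjects Number of subjects (default 9).
#' @param duration_range_s Two integers, min and max session duration in
#'   seconds (default `c(480, 846)`).
#' @param baseline_bpm_mean,baseline_bpm_sd Mean and standard deviation of the
#'   per-subject resting heart-rate baseline, in BPM (defaults 96 and 8).
#' @param state_offsets Named numeric: additive BPM shift for each affect
#'   state. Default `c(negative = 12, positive = -6, neutral = 0)` — arousal
#'   raises heart rate during negative episodes (anger, fear) and calm
#'   positive engagement lowers it slightly.
#' @param hr_noise_sd Standard deviation of additive Gaussian measurement
#'   noise on the heart-rate samples, in BPM (default 2).
#' @param sampling_rate_hz Heart-rate sampling rate in samples per second
#'   (default 1).
#' @param fps Video frame rate in frames per second (default 25).
#' @param fer_accuracy Probability that a frame prediction is drawn from the
#'   fine-emotion cluster consistent with the true latent state (default 0.8).
#' @param confidence_params List with elements `correct` and `incorrect`, each
#'   a length-2 numeric of Beta shape parameters for the prediction-confidence
#'   distribution of cluster-consistent and inconsistent frames. Defaults
#'   `Beta(8, 2)` (mean 0.8) and `Beta(2, 4)` (mean 1/3), so confidence is
#'   informative about correctness — the premise of confidence-based
#'   escalation.
#' @param dwell_mean_s Mean dwell time of the latent affect process, in
#'   seconds (default 30).
#' @param state_probs Probabilities of the three states
#'   (negative, positive, neutral) when a new episode starts (default
#'   `c(0.3, 0.3, 0.4)`).
#' @param seed Integer master seed; the whole cohort is reproducible from it.
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 2, duration_range_s = c(30, 40), seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_subjects = 9,
                          duration_range_s = c(480, 846),
                          baseline_bpm_mean = 96,
                          baseline_bpm_sd = 8,
                          state_offsets = c(negative = 12, positive = -6,
                                            neutral = 0),
                          hr_noise_sd = 2,
                          sampling_rate_hz = 1,
                          fps = 25,
                          fer_accuracy = 0.8,
                          confidence_params = list(correct = c(8, 2),
                                                   incorrect = c(2, 4)),
                          dwell_mean_s = 30,
                          state_probs = c(negative = 0.3, positive = 0.3,
                                          neutral = 0.4),
                          seed = 1L) {
  check_number(n_subjects, "n_subjects", 1)
  if (length(duration_range_s) != 2L || any(duration_range_s < 1) ||
      any(duration_range_s > 86400) ||
      duration_range_s[1] > duration_range_s[2]) {
    abort("`duration_range_s` must be (min, max) seconds within [1, 86400].")
  }
  check_number(baseline_bpm_sd, "baseline_bpm_sd", 0)
  check_number(hr_noise_sd, "hr_noise_sd", 0)
  check_number(sampling_rate_hz, "sampling_rate_hz", 1e-9)
  check_number(fps, "fps", 1e-9)
  check_probability(fer_accuracy, "fer_accuracy")
  check_simplex(unname(state_probs), "state_probs")
  check_number(dwell_mean_s, "dwell_mean_s", 1)
  missing_states <- setdiff(affect_states(), names(state_offsets))
  if (length(missing_states)) {
    abort(paste0("`state_offsets` missing state(s): ",
                 paste(missing_states, collapse = ", ")))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         duration_range_s = as.integer(duration_range_s),
         baseline_bpm_mean = baseline_bpm_mean,
         baseline_bpm_sd = baseline_bpm_sd,
         state_offsets = state_offsets,
         hr_noise_sd = hr_noise_sd,
         sampling_rate_hz = sampling_rate_hz,
         fps = fps,
         fer_accuracy = fer_accuracy,
         confidence_params = confidence_params,
         dwell_mean_s = dwell_mean_s,
         state_probs = state_probs,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a latent per-second affect state sequence
#'
#' Simulates a semi-Markov process over the three affect states: episode
#' states are drawn independently from `state_probs` and episode lengths are
#' `1 + Geometric(1 / dwell_mean_s)` seconds, so dwell times average
#' `dwell_mean_s` and every episode lasts at least one second. This is the
#' simplest process producing the contiguous affect episodes seen when a child
#' alternates between task success and frustration.
#'
#' @param duration_s Session length in whole seconds (>= 1).
#' @param dwell_mean_s Mean episode length in seconds (>= 1).
#' @param state_probs Probabilities of (negative, positive, neutral).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A tibble with one row per second: `t_s` (0-based) and `state`
#'   (factor over [affect_states()]).
#' @export
#' @examples
#' generate_state_sequence(10, state_probs = c(0, 0, 1))
generate_state_sequence <- function(duration_s,
                                    dwell_mean_s = 30,
                                    state_probs = c(negative = 0.3,
                                                    positive = 0.3,
                                                    neutral = 0.4),
                                    seed = NULL) {
  check_number(duration_s, "duration_s", 1)
  check_number(dwell_mean_s, "dwell_mean_s", 1)
  check_simplex(unname(state_probs), "state_probs")
  duration_s <- as.integer(duration_s)
  states <- with_seed(seed, {
    out <- character(0)
    p <- 1 / dwell_mean_s
    while (length(out) < duration_s) {
      dwell <- 1L + rgeom(1L, p)
      st <- sample(affect_states(), 1L, prob = unname(state_probs))
      out <- c(out, rep(st, dwell))
    }
    out[seq_len(duration_s)]
  })
  tibble::tibble(t_s = seq_len(duration_s) - 1L,
                 state = as_affect_factor(states))
}

#' Generate a heart-rate stream from a latent state sequence
#'
#' Each sample is `baseline + offset(state) + Gaussian noise`, clipped to the
#' physiological range 30–220 BPM. The state governing sample `k` (0-based) is
#' the latent state of the second containing time `k / sampling_rate_hz`.
#'
#' @param states State-sequence tibble from [generate_state_sequence()].
#' @param baseline_bpm Subject baseline heart rate, BPM.
#' @param state_offsets Named numeric BPM shift per affect state; all three
#'   states must be present.
#' @param noise_sd Gaussian noise standard deviation, BPM (>= 0).
#' @param sampling_rate_hz Samples per second (default 1).
#' @param seed Optional integer seed.
#' @param t0 Stream start time in seconds (default 0).
#'
#' @return Tibble with columns `t_s` and `bpm`, one row per sample.
#' @export
#' @examples
#' seq10 <- generate_state_sequence(10, state_probs = c(0, 0, 1))
#' generate_hr(seq10, baseline_bpm = 96.8,
#'             state_offsets = c(negative = 12, positive = -6, neutral = 0),
#'             noise_sd = 0)
generate_hr <- function(states, baseline_bpm, state_offsets, noise_sd,
                        sampling_rate_hz = 1, seed = NULL, t0 = 0) {
  check_number(noise_sd, "noise_sd", 0)
  check_number(sampling_rate_hz, "sampling_rate_hz", 1e-9)
  missing_states <- setdiff(levels(states$state), names(state_offsets))
  if (length(missing_states)) {
    abort(paste0("`state_offsets` missing state(s): ",
                 paste(missing_states, collapse = ", ")))
  }
  duration_s <- nrow(states)
  n <- as.integer(round(duration_s * sampling_rate_hz))
  k <- seq_len(n) - 1L
  sec <- pmin(floor(k / sampling_rate_hz), duration_s - 1L) + 1L
  mu <- baseline_bpm + unname(state_offsets[as.character(states$state[sec])])
  noise <- if (noise_sd > 0) {
    with_seed(seed, rnorm(n, 0, noise_sd))
  } else {
    numeric(n)
  }
  tibble::tibble(t_s = t0 + k / sampling_rate_hz,
                 bpm = pmin(pmax(mu + noise, 30), 220))
}

#' Generate a frame-level facial-expression prediction stream
#'
#' Emits one prediction per video frame. With probability `fer_accuracy` the
#' fine label is drawn uniformly from the fine-emotion cluster consistent with
#' the true latent state (negative -> fear/anger/sadness/disgust, positive ->
#' happiness, neutral -> neutral); otherwise it is drawn uniformly from the
#' remaining fine labels, which includes surprise and contempt — those two
#' never arise as consistent predictions because the three-class clustering
#' leaves them unassigned. Confidences come from the `correct` Beta
#' distribution for consistent frames and the `incorrect` one otherwise.
#'
#' @param states State-sequence tibble from [generate_state_sequence()].
#' @param fps Frames per second (default 25).
#' @param fer_accuracy Probability of a cluster-consistent prediction.
#' @param confidence_params List with Beta shape pairs `correct` and
#'   `incorrect` (see [cohort_config()]).
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `frame_index` (0-based), `label` (factor over
#'   [fine_emotions()]), `confidence` in \[0, 1\], and `consistent` (logical,
#'   whether the frame was drawn from the true state's cluster).
#' @export
generate_fer_stream <- function(states, fps = 25, fer_accuracy = 0.8,
                                confidence_params = list(correct = c(8, 2),
                                                         incorrect = c(2, 4)),
                                seed = NULL) {
  check_number(fps, "fps", 1e-9)
  check_probability(fer_accuracy, "fer_accuracy")
  duration_s <- nrow(states)
  n_frames <- as.integer(round(duration_s * fps))
  frame <- seq_len(n_frames) - 1L
  sec <- pmin(floor(frame / fps), duration_s - 1L) + 1L
  true_state <- as.character(states$state[sec])
  clusters <- cluster_consistent_labels()
  with_seed(seed, {
    consistent <- runif(n_frames) < fer_accuracy
    label <- character(n_frames)
    for (st in affect_states()) {
      in_cluster <- clusters[[st]]
      out_cluster <- setdiff(fine_emotions(), in_cluster)
      i_con <- which(consistent & true_state == st)
      i_inc <- which(!consistent & true_state == st)
      if (length(i_con)) {
        label[i_con] <- sample(in_cluster, length(i_con), replace = TRUE)
      }
      if (length(i_inc)) {
        label[i_inc] <- sample(out_cluster, length(i_inc), replace = TRUE)
      }
    }
    confidence <- numeric(n_frames)
    pc <- confidence_params$correct
    pi_ <- confidence_params$incorrect
    confidence[consistent] <- rbeta(sum(consistent), pc[1], pc[2])
    confidence[!consistent] <- rbeta(sum(!consistent), pi_[1], pi_[2])
    tibble::tibble(frame_index = frame,
                   label = as_fine_factor(label),
                   confidence = confidence,
                   consistent = consistent)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws one session per subject: a duration uniform over
#' `duration_range_s`, a subject baseline from
#' `Normal(baseline_bpm_mean, baseline_bpm_sd)`, then the latent state
#' sequence, heart-rate stream and frame-prediction stream. The ground-truth
#' state sequence is kept alongside so downstream stages can be scored against
#' it. Bit-identical output is guaranteed for identical configs.
#'
#' @param config A [cohort_config()].
#'
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `duration_s`, `baseline_bpm`, and list-columns `truth` (state sequence),
#'   `hr` (heart-rate stream) and `fer` (frame predictions).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 2,
#'                                         duration_range_s = c(20, 30),
#'                                         seed = 7))
#' cohort$duration_s
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  seeds <- matrix(derive_seeds(config$seed, 5L * n), nrow = n)
  durations <- with_seed(config$seed, {
    # subject-level draws come straight from the master seed stream
    choices <- seq(config$duration_range_s[1], config$duration_range_s[2])
    d <- choices[sample.int(length(choices), n, replace = TRUE)]
    b <- rnorm(n, config$baseline_bpm_mean, config$baseline_bpm_sd)
    list(duration_s = d, baseline = b)
  })
  sessions <- purrr::map(seq_len(n), function(i) {
    truth <- generate_state_sequence(durations$duration_s[i],
                                     dwell_mean_s = config$dwell_mean_s,
                                     state_probs = config$state_probs,
                                     seed = seeds[i, 2])
    hr <- generate_hr(truth,
                      baseline_bpm = durations$baseline[i],
                      state_offsets = config$state_offsets,
                      noise_sd = config$hr_noise_sd,
                      sampling_rate_hz = config$sampling_rate_hz,
                      seed = seeds[i, 3])
    fer <- generate_fer_stream(truth,
                               fps = config$fps,
                               fer_accuracy = config$fer_accuracy,
                               confidence_params = config$confidence_params,
                               seed = seeds[i, 4])
    list(truth = truth, hr = hr, fer = fer)
  })
  tibble::tibble(
    subject_id = sprintf("P%d", seq_len(n)),
    duration_s = as.integer(durations$duration_s),
    baseline_bpm = durations$baseline,
    truth = purrr::map(sessions, "truth"),
    hr = purrr::map(sessions, "hr"),
    fer = purrr::map(sessions, "fer")
  )
}

#' Write a cohort to disk as plain CSV files
#'
#' Writes `hr_<subject>.csv` (`t_s, bpm`), `fer_<subject>.csv`
#' (`frame_index, label, confidence`), `truth_<subject>.csv` (`t_s, state`)
#' and a `manifest.json` echoing the file list.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param config Optional [cohort_config()] echoed into the manifest.
#'
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::map(seq_len(nrow(cohort)), function(i) {
    id <- cohort$subject_id[i]
    hr_path <- file.path(dir, sprintf("hr_%s.csv", id))
    fer_path <- file.path(dir, sprintf("fer_%s.csv", id))
    truth_path <- file.path(dir, sprintf("truth_%s.csv", id))
    write.csv(cohort$hr[[i]], hr_path, row.names = FALSE)
    fer <- cohort$fer[[i]][c("frame_index", "label", "confidence")]
    write.csv(fer, fer_path, row.names = FALSE)
    truth <- cohort$truth[[i]]
    write.csv(data.frame(t_s = truth$t_s, state = as.character(truth$state)),
              truth_path, row.names = FALSE)
    list(subject_id = id, hr = basename(hr_path), fer = basename(fer_path),
         truth = basename(truth_path))
  })
  manifest <- list(subjects = files)
  if (!is.null(config)) {
    manifest$config <- unclass(config)
    manifest$seed <- config$seed
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV files and `manifest.json`.
#' @return A cohort tibble with the same list-columns as [generate_cohort()]
#'   (`consistent` is absent from re-read prediction streams; baselines are
#'   not recoverable from disk and are `NA`).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  rows <- purrr::map(manifest$subjects, function(s) {
    hr <- tibble::as_tibble(read.csv(file.path(dir, s$hr)))
    fer <- tibble::as_tibble(read.csv(file.path(dir, s$fer)))
    fer$label <- as_fine_factor(fer$label)
    truth <- tibble::as_tibble(read.csv(file.path(dir, s$truth)))
    truth$state <- as_affect_factor(truth$state)
    tibble::tibble(subject_id = s$subject_id,
                   duration_s = nrow(truth),
                   baseline_bpm = NA_real_,
                   truth = list(truth), hr = list(hr), fer = list(fer))
  })
  dplyr::bind_rows(rows)
}
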