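make_fer <- function(labels, conf) {
  tibble::tibble(frame_index = seq_along(labels) - 1L,
                 label = factor(labels, levels = fine_emotions()),
                 confidence = conf)
}

test_that("clip segmentation uses floor semantics and exact clip lengths", {
  s <- generate_state_sequence(5, state_probs = c(0, 0, 1))
  fer <- generate_fer_stream(s, fps = 25, fer_accuracy = 1, seed = 1)

  # 125 frames at nf = 50: two clips, 25 frames discarded
  clips <- segment_clips(fer, fps = 25, window_s = 2)
  expect_equal(nrow(clips), 100)
  expect_equal(unique(clips$clip_index), c(0L, 1L))
  expect_equal(clips$frame_index[clips$clip_index == 0], 0:49)
  expect_equal(clips$frame_index[clips$clip_index == 1], 50:99)
  expect_equal(unique(clips$start_time_s), c(0, 2))

  # exact division: 100 frames -> 2 clips, nothing discarded
  clips4 <- segment_clips(fer[1:100, ], fps = 25, window_s = 2)
  expect_equal(nrow(clips4), 100)

  expect_error(segment_clips(fer, fps = 25, window_s = 0.03), "whole number")
  expect_error(segment_clips(fer[0, ], fps = 25, window_s = 2), "empty")
})

test_that("the representative frame follows mode first, then confidence", {
  # unanimous clip
  una <- make_fer(rep("happiness", 50), rep(0.9, 50)) |>
    dplyr::mutate(clip_index = 0L)
  rep1 <- select_representative(una)
  expect_equal(as.character(rep1$fine_label), "happiness")
  expect_equal(rep1$confidence, 0.9)

  # mode beats raw confidence: 3 neutral vs 2 high-confidence fear
  mixed <- make_fer(c("neutral", "neutral", "neutral", "fear", "fear"),
                    c(0.5, 0.7, 0.6, 0.99, 0.98)) |>
    dplyr::mutate(clip_index = 0L)
  rep2 <- select_representative(mixed)
  expect_equal(as.character(rep2$fine_label), "neutral")
  expect_equal(rep2$confidence, 0.7)
  expect_equal(rep2$frame_index, 1L)

  # exact modal tie with equal best confidences: lowest frame index wins
  tie <- make_fer(c(rep("happiness", 25), rep("sadness", 25)),
                  c(0.8, rep(0.1, 24), 0.8, rep(0.1, 24))) |>
    dplyr::mutate(clip_index = 0L)
  rep3 <- select_representative(tie)
  expect_equal(as.character(rep3$fine_label), "happiness")
  expect_equal(rep3$frame_index, 0L)
})

test_that("representative selection agrees with brute force on random clips", {
  set.seed(101)
  for (i in 1:500) {
    clip <- random_clip(nf = sample(c(4, 10, 50), 1))
    got <- select_representative(clip)
    want <- oracle_representative(clip)
    expect_equal(got$frame_index, want$frame_index)
    expect_equal(as.character(got$fine_label), want$fine_label)
    expect_equal(got$confidence, want$confidence)
  }
})

test_that("fine emotions map totally onto the three affect classes", {
  expect_equal(as.character(map_to_affect("fear")), "negative")
  expect_equal(as.character(map_to_affect("happiness")), "positive")
  expect_equal(as.character(map_to_affect("neutral")), "neutral")
  expect_equal(as.character(map_to_affect("surprise")), "positive")
  expect_equal(as.character(map_to_affect("contempt")), "negative")

  all_mapped <- map_to_affect(fine_emotions())
  expect_false(anyNA(all_mapped))
  expect_setequal(as.character(unique(all_mapped)), affect_states())

  expect_equal(as.character(
    map_to_affect("surprise", extension = c(surprise = "neutral"))),
    "neutral")
  expect_error(map_to_affect("boredom"), "Unknown")
  expect_error(map_to_affect("fear", extension = c(fear = "positive")),
               "surprise")
})

test_that("escalation routes low-confidence clips to the human oracle", {
  reps <- tibble::tibble(clip_index = 0:1,
                         frame_index = c(10L, 60L),
                         fine_label = factor(c("happiness", "fear"),
                                             levels = fine_emotions()),
                         confidence = c(0.9, 0.3))
  oracle_calls <- 0L
  oracle <- function(rep_frame, context) {
    oracle_calls <<- oracle_calls + 1L
    "negative"
  }
  out <- decide_escalation(reps, threshold = 0.5, oracle = oracle)
  expect_equal(as.character(out$affect), c("positive", "negative"))
  expect_equal(as.character(out$provenance), c("auto", "human"))
  expect_equal(oracle_calls, 1L)

  # boundary: confidence equal to the threshold stays automatic
  at_boundary <- decide_escalation(
    dplyr::mutate(reps, confidence = c(0.5, 0.5)), threshold = 0.5)
  expect_true(all(at_boundary$provenance == "auto"))

  expect_error(decide_escalation(reps, threshold = 0.5), "oracle")
  bad_oracle <- function(rep_frame, context) stop("annotator unavailable")
  expect_error(decide_escalation(reps, threshold = 0.5, oracle = bad_oracle),
               "clip 1")
})

test_that("escalated fraction sweeps from 0 to 1 and is monotone", {
  s <- generate_state_sequence(120, dwell_mean_s = 10, seed = 4)
  fer <- generate_fer_stream(s, fps = 25, fer_accuracy = 0.7, seed = 5)
  reps <- select_representative(segment_clips(fer, fps = 25, window_s = 2))
  oracle <- truth_oracle(s, window_s = 2)
  fractions <- vapply(seq(0, 1, by = 0.1), function(th) {
    out <- decide_escalation(reps, threshold = th, oracle = oracle)
    mean(out$provenance == "human")
  }, numeric(1))
  expect_equal(fractions[1], 0)
  expect_equal(fractions[11], 1)
  expect_true(all(diff(fractions) >= 0))
})

test_that("synchronization aligns window k with clip k and takes the min", {
  s <- generate_state_sequence(828, dwell_mean_s = 30, seed = 6)
  hr <- generate_hr(s, 96, c(negative = 12, positive = -6, neutral = 0), 2,
                    seed = 7)
  fer <- generate_fer_stream(s, fps = 25, fer_accuracy = 0.9, seed = 8)
  labels <- fer |>
    segment_clips(fps = 25, window_s = 2) |>
    select_representative() |>
    decide_escalation(threshold = 0, oracle = NULL)
  expect_equal(nrow(labels), 414)
  windows <- synchronize(hr, labels, window_s = 2)
  expect_equal(nrow(windows), 414)
  expect_true(all(lengths(windows$hr_vector) == 2))
  expect_equal(windows$hr_vector[[2]], hr$bpm[3:4])

  # HR shorter than the video: HR-limited window count
  short <- synchronize(hr[1:10, ], labels, window_s = 2)
  expect_equal(nrow(short), 5)
  expect_error(synchronize(hr[1, ], labels, window_s = 2), "No overlapping")
})

test_that("a perfect recognizer reproduces the modal ground truth", {
  cohort <- generate_cohort(cohort_config(
    n_subjects = 1, duration_range_s = c(200, 200), fer_accuracy = 1,
    hr_noise_sd = 1, seed = 31))
  labeled <- annotate_cohort(cohort, window_s = 2, threshold = 0)
  truth <- cohort$truth[[1]]
  modal <- vapply(labeled$window_index, function(k) {
    span <- truth$state[truth$t_s >= 2 * k & truth$t_s < 2 * (k + 1)]
    names(which.max(table(span)))
  }, character(1))
  # windows whose 2 s span is state-pure must match exactly; mixed windows
  # may differ only through the modal-tie convention
  pure <- vapply(labeled$window_index, function(k) {
    span <- truth$state[truth$t_s >= 2 * k & truth$t_s < 2 * (k + 1)]
    length(unique(span)) == 1L
  }, logical(1))
  expect_true(all(as.character(labeled$affect)[pure] == modal[pure]))
  expect_gte(mean(as.character(labeled$affect) == modal), mean(pure))
  expect_true(all(labeled$provenance == "auto"))
})

test_that("window counts are conserved across provenance classes", {
  cohort <- small_cohort(seed = 41)
  labeled <- annotate_cohort(cohort, window_s = 2, threshold = 0.9)
  for (i in seq_len(nrow(cohort))) {
    sub <- labeled[labeled$subject_id == cohort$subject_id[i], ]
    n_clips <- (cohort$duration_s[i] * 25) %/% 50
    n_hr_windows <- cohort$duration_s[i] %/% 2
    expect_equal(nrow(sub), min(n_clips, n_hr_windows))
    expect_equal(sum(sub$provenance == "auto") +
                   sum(sub$provenance == "human"), nrow(sub))
  }
})
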