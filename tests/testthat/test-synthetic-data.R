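test_that("state sequence respects degenerate simplices and the seed", {
  seq10 <- generate_state_sequence(10, state_probs = c(0, 0, 1))
  expect_equal(nrow(seq10), 10)
  expect_true(all(seq10$state == "neutral"))

  a <- generate_state_sequence(600, dwell_mean_s = 30, seed = 1)
  b <- generate_state_sequence(600, dwell_mean_s = 30, seed = 1)
  expect_identical(a, b)
  expect_error(generate_state_sequence(10, state_probs = c(0.5, 0.5, 0.5)),
               "simplex|summing")
})

test_that("long-run state frequencies match the episode distribution", {
  # short dwell so the run contains thousands of independent episodes;
  # the episode count, not the second count, drives convergence
  probs <- c(negative = 0.3, positive = 0.2, neutral = 0.5)
  s <- generate_state_sequence(20000, dwell_mean_s = 5,
                               state_probs = probs, seed = 42)
  freq <- as.numeric(table(s$state) / nrow(s))
  expect_true(all(abs(freq - unname(probs)) < 0.02))
})

test_that("dwell episodes last at least one second", {
  s <- generate_state_sequence(2000, dwell_mean_s = 3, seed = 9)
  runs <- rle(as.character(s$state))
  expect_true(all(runs$lengths >= 1))
  # mean dwell should be in the right ballpark (runs of equal states can
  # merge adjacent episodes, so observed means exceed the nominal 3 s)
  expect_gt(mean(runs$lengths), 2)
})

test_that("heart-rate generation maps states to exact levels without noise", {
  seq10 <- generate_state_sequence(10, state_probs = c(0, 0, 1))
  hr <- generate_hr(seq10, baseline_bpm = 96.8,
                    state_offsets = c(negative = 12, positive = -6,
                                      neutral = 0),
                    noise_sd = 0)
  expect_equal(hr$bpm, rep(96.8, 10))

  s <- generate_state_sequence(300, dwell_mean_s = 5, seed = 3)
  hr <- generate_hr(s, baseline_bpm = 90,
                    state_offsets = c(negative = 10, positive = -5,
                                      neutral = 0),
                    noise_sd = 0)
  expected <- c(negative = 100, positive = 85, neutral = 90)
  expect_equal(hr$bpm, unname(expected[as.character(s$state)]))
  expect_error(generate_hr(s, 90, c(negative = 1, positive = 2), 0),
               "missing state")
})

test_that("noisy heart rate is unbiased and clipped to physiology", {
  s <- generate_state_sequence(10000, state_probs = c(0, 0, 1))
  hr <- generate_hr(s, baseline_bpm = 96.8,
                    state_offsets = c(negative = 0, positive = 0, neutral = 0),
                    noise_sd = 3, seed = 8)
  expect_lt(abs(mean(hr$bpm) - 96.8), 0.1)
  hr_low <- generate_hr(s, baseline_bpm = 31,
                        state_offsets = c(negative = 0, positive = 0,
                                          neutral = 0),
                        noise_sd = 5, seed = 8)
  expect_true(all(hr_low$bpm >= 30 & hr_low$bpm <= 220))
})

test_that("heart-rate length scales with the sampling rate", {
  s <- generate_state_sequence(20, state_probs = c(0, 0, 1))
  for (rate in c(1, 2, 5)) {
    hr <- generate_hr(s, 96, c(negative = 0, positive = 0, neutral = 0), 0,
                      sampling_rate_hz = rate)
    expect_equal(nrow(hr), 20 * rate)
  }
})

test_that("prediction stream is perfect, adversarial, or calibrated", {
  pos <- generate_state_sequence(4, state_probs = c(0, 1, 0))
  fer <- generate_fer_stream(pos, fps = 25, fer_accuracy = 1, seed = 1)
  expect_equal(nrow(fer), 100)
  expect_true(all(fer$label == "happiness"))

  neu <- generate_state_sequence(4, state_probs = c(0, 0, 1))
  fer0 <- generate_fer_stream(neu, fps = 25, fer_accuracy = 0, seed = 1)
  expect_false(any(fer0$label == "neutral"))

  long <- generate_state_sequence(2000, dwell_mean_s = 10, seed = 2)
  fer8 <- generate_fer_stream(long, fps = 25, fer_accuracy = 0.8, seed = 3)
  expect_equal(nrow(fer8), 50000)
  clusters <- affecthr:::cluster_consistent_labels()
  sec <- pmin(fer8$frame_index %/% 25, 1999) + 1
  true_state <- as.character(long$state[sec])
  consistent <- mapply(function(lab, st) lab %in% clusters[[st]],
                       as.character(fer8$label), true_state)
  expect_lt(abs(mean(consistent) - 0.8), 0.01)
  expect_identical(consistent, fer8$consistent, ignore_attr = TRUE)
  expect_true(all(fer8$confidence >= 0 & fer8$confidence <= 1))
})

test_that("confidence distinguishes consistent from inconsistent frames", {
  s <- generate_state_sequence(500, dwell_mean_s = 10, seed = 5)
  fer <- generate_fer_stream(s, fps = 25, fer_accuracy = 0.5, seed = 6)
  expect_gt(mean(fer$confidence[fer$consistent]),
            mean(fer$confidence[!fer$consistent]) + 0.2)
})

test_that("cohort generation is reproducible and within the study envelope", {
  cfg <- cohort_config(seed = 17)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 9)
  expect_true(all(cohort$duration_s >= 480 & cohort$duration_s <= 846))
  for (i in seq_len(9)) {
    expect_equal(nrow(cohort$hr[[i]]), cohort$duration_s[i])
    expect_equal(nrow(cohort$fer[[i]]), cohort$duration_s[i] * 25)
    expect_true(all(cohort$hr[[i]]$bpm >= 30 & cohort$hr[[i]]$bpm <= 220))
  }
  expect_identical(cohort, generate_cohort(cohort_config(seed = 17)))
  expect_false(identical(cohort, generate_cohort(cohort_config(seed = 18))))

  one <- generate_cohort(cohort_config(n_subjects = 1,
                                       duration_range_s = c(10, 10),
                                       seed = 1))
  expect_equal(one$duration_s, 10L)
  expect_equal(nrow(one$hr[[1]]), 10)
})

test_that("cohort grand-mean heart rate is calibrated to the target", {
  means <- vapply(1:5, function(seed) {
    cohort <- generate_cohort(cohort_config(
      n_subjects = 9, duration_range_s = c(120, 200),
      baseline_bpm_mean = 96, baseline_bpm_sd = 8,
      state_offsets = c(negative = 12, positive = -6, neutral = 0),
      seed = seed))
    mean(unlist(lapply(cohort$hr, function(h) h$bpm)))
  }, numeric(1))
  # averaged over seeds: a single 9-subject cohort carries ~2.7 BPM of
  # baseline sampling noise in its grand mean
  expect_gte(mean(means), 90)
  expect_lte(mean(means), 104)
  expect_true(all(means > 85 & means < 110))
})

test_that("cohorts round-trip through CSV on disk", {
  dir <- withr::local_tempdir()
  cohort <- small_cohort(seed = 23)
  cfg <- cohort_config(n_subjects = 2, duration_range_s = c(40, 60),
                       seed = 23)
  write_cohort(cohort, dir, cfg)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(back$subject_id, cohort$subject_id)
  for (i in 1:2) {
    expect_equal(back$hr[[i]]$bpm, cohort$hr[[i]]$bpm)
    expect_equal(as.character(back$fer[[i]]$label),
                 as.character(cohort$fer[[i]]$label))
    expect_equal(back$truth[[i]]$state, cohort$truth[[i]]$state)
  }
})
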