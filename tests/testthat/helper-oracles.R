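# Independent oracles used to cross-check the implementation. These are
# written as naive, obviously-correct loops and share no code with R/.

# Brute-force representative-frame selection: scan all frames, score each by
# (its label's frequency in the clip, its confidence, -frame_index) and pick
# the lexicographic maximum.
oracle_representative <- function(clip) {
  labels <- as.character(clip$label)
  counts <- table(labels)
  best <- NULL
  for (i in seq_len(nrow(clip))) {
    score <- c(counts[[labels[i]]], clip$confidence[i], -clip$frame_index[i])
    if (is.null(best)) {
      best <- i; best_score <- score
    } else {
      for (j in 1:3) {
        if (score[j] > best_score[j]) { best <- i; best_score <- score; break }
        if (score[j] < best_score[j]) break
      }
    }
  }
  list(frame_index = clip$frame_index[best],
       fine_label = labels[best],
       confidence = clip$confidence[best])
}

# Naive convolution-and-decimate orthonormal Haar analysis step.
oracle_haar_step <- function(s) {
  h <- c(1, 1) / sqrt(2)   # low-pass
  g <- c(1, -1) / sqrt(2)  # high-pass
  m <- length(s) / 2
  approx <- detail <- numeric(m)
  for (i in seq_len(m)) {
    seg <- s[(2 * i - 1):(2 * i)]
    approx[i] <- sum(h * seg)
    detail[i] <- sum(g * seg)
  }
  list(approx = approx, detail = detail)
}

oracle_multilevel <- function(s, levels) {
  details <- list()
  a <- s
  for (l in seq_len(levels)) {
    step <- oracle_haar_step(a)
    details[[l]] <- step$detail
    a <- step$approx
  }
  list(approx = a, details = details)
}

# A random clip tibble; with prob `tie_prob` it is built to contain an exact
# modal tie (two labels at equal top frequency).
random_clip <- function(nf = 50, tie_prob = 0.3) {
  labels <- sample(fine_emotions(), nf, replace = TRUE)
  if (runif(1) < tie_prob && nf >= 4) {
    half <- nf %/% 2
    labels <- c(rep(sample(fine_emotions(), 1), half),
                rep(sample(fine_emotions(), 1), nf - half))
  }
  conf <- round(runif(nf), 2)  # rounding manufactures confidence ties
  tibble::tibble(frame_index = seq_len(nf) - 1L,
                 label = factor(labels, levels = fine_emotions()),
                 confidence = conf,
                 clip_index = 0L)
}

small_cohort <- function(n_subjects = 2, duration = c(40, 60), seed = 11,
                         ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                duration_range_s = duration, seed = seed,
                                ...))
}
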