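#' One orthonormal Haar analysis step
#'
#' Splits a signal into its approximation (low-pass) and detail (high-pass)
#' half-bands: `approx[i] = (s[2i-1] + s[2i]) / sqrt(2)` and
#' `detail[i] = (s[2i-1] - s[2i]) / sqrt(2)`. The `1/sqrt(2)` normalization
#' makes the filter bank orthonormal, so energy is conserved exactly
#' (Parseval) and the inverse step is the transpose.
#'
#' @param signal Numeric vector of even length >= 2.
#'
#' @return List with numeric vectors `approx` and `detail`, each half the
#'   input length.
#' @export
#' @examples
#' haar_step(c(4, 2))   # (4+2)/sqrt(2), (4-2)/sqrt(2)
haar_step <- function(signal) {
  m <- length(signal)
  if (m < 2L || m %% 2L != 0L) {
    abort("`signal` must have even length >= 2.")
  }
  odd <- signal[seq(1L, m, by = 2L)]
  even <- signal[seq(2L, m, by = 2L)]
  list(approx = (odd + even) / sqrt(2),
       detail = (odd - even) / sqrt(2))
}

#' Multi-level Haar decomposition (sub-band coding)
#'
#' Applies [haar_step()] recursively to successive approximations: each level
#' halves the number of samples, producing detail bands `D1 .. DL` and the
#' final approximation `AL`. Only those bands are retained — together they are
#' a critically sampled, invertible representation of the window.
#'
#' Odd-length bands cannot be halved; by default (`pad = "repeat"`) the last
#' sample is repeated once before the step, while `pad = "strict"` raises an
#' error instead. Padding keeps short non-dyadic windows usable but breaks
#' exact energy conservation and critical sampling.
#'
#' @param window Numeric vector (a heart-rate window), length >= 2.
#' @param levels Decomposition depth `L`; defaults to the maximal
#'   `floor(log2(length(window)))`.
#' @param pad `"repeat"` (default) or `"strict"` handling of odd band lengths.
#'
#' @return Object of class `haar_dwt`: list with `approx` (the `AL` band),
#'   `details` (list `D1 .. DL`), `levels`, `n` (input length) and `padded`.
#' @export
#' @examples
#' multilevel_dwt(c(1, 1, 1, 1), levels = 2)
multilevel_dwt <- function(window, levels = NULL,
                           pad = c("repeat", "strict")) {
  pad <- match.arg(pad)
  n <- length(window)
  if (n < 2L) abort("`window` must have length >= 2 for the DWT.")
  max_level <- floor(log2(n))
  if (is.null(levels)) levels <- max_level
  check_number(levels, "levels", 1)
  if (pad == "strict" && levels > max_level) {
    abort(sprintf("`levels` = %d exceeds the maximum depth %d for length %d.",
                  levels, max_level, n))
  }
  approx <- window
  details <- vector("list", levels)
  padded <- FALSE
  for (l in seq_len(levels)) {
    if (length(approx) < 2L) {
      abort(sprintf(
        "Band at level %d has a single sample; maximum depth is %d.",
        l, l - 1L))
    }
    if (length(approx) %% 2L != 0L) {
      if (pad == "strict") {
        abort(sprintf("Odd band length %d at level %d (strict mode).",
                      length(approx), l))
      }
      approx <- c(approx, approx[length(approx)])
      padded <- TRUE
    }
    step <- haar_step(approx)
    details[[l]] <- step$detail
    approx <- step$approx
  }
  structure(list(approx = approx, details = details,
                 levels = as.integer(levels), n = n, padded = padded),
            class = "haar_dwt")
}

#' Inverse multi-level Haar transform
#'
#' Reconstructs the signal from a [multilevel_dwt()] decomposition by running
#' the orthonormal synthesis step level by level:
#' `s[2i-1] = (a[i] + d[i]) / sqrt(2)`, `s[2i] = (a[i] - d[i]) / sqrt(2)`.
#' Reconstruction is exact (to floating-point) for decompositions that did not
#' pad; padded decompositions reconstruct the padded signal, which is then
#' truncated back to the original length.
#'
#' @param dec A `haar_dwt` object.
#'
#' @return Numeric vector of length `dec$n`.
#' @export
#' @examples
#' w <- c(96, 99, 97, 95)
#' inverse_dwt(multilevel_dwt(w))  # recovers w
inverse_dwt <- function(dec) {
  stopifnot(inherits(dec, "haar_dwt"))
  approx <- dec$approx
  for (l in rev(seq_len(dec$levels))) {
    detail <- dec$details[[l]]
    if (length(approx) == length(detail) + 1L && dec$padded) {
      # drop the repeat-pad tail reconstructed at the finer level
      approx <- approx[seq_len(length(detail))]
    }
    if (length(approx) != length(detail)) {
      abort("Inconsistent band lengths in decomposition.")
    }
    m <- length(detail)
    a <- approx[seq_len(m)]
    s <- numeric(2L * m)
    s[seq(1L, 2L * m, by = 2L)] <- (a + detail) / sqrt(2)
    s[seq(2L, 2L * m, by = 2L)] <- (a - detail) / sqrt(2)
    approx <- s
  }
  approx[seq_len(dec$n)]
}

#' Flatten a decomposition into a feature vector
#'
#' Concatenates `[AL, DL, ..., D1]`. For dyadic window lengths without
#' padding the result has exactly the window length (critical sampling).
#'
#' @param dec A `haar_dwt` object.
#' @return Numeric vector of coefficients.
#' @export
dwt_coefficients <- function(dec) {
  stopifnot(inherits(dec, "haar_dwt"))
  c(dec$approx, unlist(rev(dec$details), use.names = FALSE))
}

#' Per-band summary statistics of a decomposition
#'
#' An alternative, lower-dimensional feature set: energy, mean and standard
#' deviation of each retained band (`AL`, `DL`, ..., `D1`). The standard
#' deviation of a single-sample band is reported as 0.
#'
#' @param dec A `haar_dwt` object.
#' @return Named numeric vector, three statistics per band.
#' @export
dwt_band_stats <- function(dec) {
  stopifnot(inherits(dec, "haar_dwt"))
  bands <- c(list(AL = dec$approx),
             setNames(rev(dec$details),
                      paste0("D", rev(seq_len(dec$levels)))))
  out <- purrr::imap(bands, function(b, nm) {
    s <- if (length(b) > 1L) sd(b) else 0
    setNames(c(sum(b^2), mean(b), s),
             paste0(nm, c("_energy", "_mean", "_sd")))
  })
  unlist(out, use.names = TRUE)
}

#' Assemble classifier-ready features from labeled windows
#'
#' Turns the labeled heart-rate windows of [annotate_cohort()] into a wide
#' feature table. With `scheme = "raw_hr"` the features are the window's
#' heart-rate samples verbatim; with `scheme = "dwt"` they are the
#' concatenated Haar sub-band coefficients (or per-band statistics when
#' `band_stats = TRUE`). Labels and provenance are carried through unchanged.
#'
#' @param windows Labeled-window tibble with list-column `hr_vector` and
#'   columns `affect` (and optionally `subject_id`, `window_index`,
#'   `provenance`).
#' @param scheme `"raw_hr"` or `"dwt"`.
#' @param levels DWT depth; `NULL` for maximal (see [multilevel_dwt()]).
#' @param band_stats Use per-band energy/mean/sd instead of raw coefficients
#'   (DWT scheme only).
#' @param zscore_by_subject Z-score each subject's samples before featurizing
#'   (off by default; the pipeline standardizes per training fold instead).
#'
#' @return Tibble with the carried id/label columns, a `scheme` column and
#'   feature columns `f1 .. fk` (equal length for all rows).
#' @export
assemble_features <- function(windows, scheme = c("raw_hr", "dwt"),
                              levels = NULL, band_stats = FALSE,
                              zscore_by_subject = FALSE) {
  scheme <- match.arg(scheme)
  lens <- lengths(windows$hr_vector)
  if (length(unique(lens)) != 1L) {
    abort("All `hr_vector` entries must have the same length.")
  }
  n <- lens[1]
  if (scheme == "dwt" && n < 2L) {
    abort("DWT features need windows of at least 2 samples.")
  }
  vectors <- windows$hr_vector
  if (zscore_by_subject) {
    if (!"subject_id" %in% names(windows)) {
      abort("`zscore_by_subject` needs a `subject_id` column.")
    }
    vectors <- split(seq_along(vectors), windows$subject_id) |>
      purrr::map(function(idx) {
        all_v <- unlist(vectors[idx])
        mu <- mean(all_v)
        s <- sd(all_v)
        if (!is.finite(s) || s == 0) s <- 1
        purrr::map(vectors[idx], function(v) (v - mu) / s)
      }) |>
      unsplit_list(windows$subject_id, length(vectors))
  }
  feats <- switch(scheme,
    raw_hr = vectors,
    dwt = purrr::map(vectors, function(v) {
      dec <- multilevel_dwt(v, levels = levels)
      if (band_stats) unname(dwt_band_stats(dec)) else dwt_coefficients(dec)
    })
  )
  k <- length(feats[[1]])
  mat <- do.call(rbind, feats)
  colnames(mat) <- paste0("f", seq_len(k))
  carried <- intersect(c("subject_id", "window_index", "affect", "provenance"),
                       names(windows))
  dplyr::bind_cols(windows[carried],
                   tibble::tibble(scheme = scheme),
                   tibble::as_tibble(mat))
}

# Reassemble a per-group list-of-lists back into original order.
unsplit_list <- function(groups, f, n) {
  out <- vector("list", n)
  idx <- split(seq_len(n), f)
  for (g in names(groups)) out[idx[[g]]] <- groups[[g]]
  out
}
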