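# Internal validation and seeding helpers.

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, 0, 1)

check_simplex <- function(p, name, tol = 1e-8) {
  if (!is.numeric(p) || length(p) != 3L || anyNA(p) || any(p < 0) ||
      abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must be three non-negative probabilities summing to 1.",
                  name))
  }
  invisible(p)
}

# Derive independent child seeds from one master seed without disturbing the
# caller's RNG state. Values stay below 2^31 (R integers).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
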