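#' The three coarse affect classes
#'
#' The pipeline classifies every heart-rate window into one of three affective
#' states: `negative`, `positive` or `neutral`. The set is closed; every label
#' column in the package uses a factor with exactly these levels.
#'
#' @return Character vector of the three affect states, in canonical order.
#' @export
#' @examples
#' affect_states()
affect_states <- function() c("negative", "positive", "neutral")

#' The eight fine facial-expression classes
#'
#' The frame-level expression recognizer distinguishes the six basic
#' expressions plus `neutral` and `contempt`. These are the admissible values
#' of the `label` column of a frame-prediction stream.
#'
#' @return Character vector of the eight fine emotion labels.
#' @export
#' @examples
#' fine_emotions()
fine_emotions <- function() {
  c("fear", "anger", "sadness", "disgust", "surprise",
    "happiness", "neutral", "contempt")
}

#' Default clustering of fine emotions into affect classes
#'
#' Fear, anger, sadness and disgust form the negative cluster; happiness the
#' positive cluster; neutral maps to neutral. Surprise and contempt are not
#' assigned by the clustering rule, so their mapping is a configurable
#' extension (see [map_to_affect()]); the defaults here send surprise to
#' positive (children often look surprised when a task succeeds) and contempt
#' to negative.
#'
#' @return Named character vector: fine emotion -> affect state.
#' @export
default_affect_map <- function() {
  c(fear = "negative", anger = "negative", sadness = "negative",
    disgust = "negative", happiness = "positive", neutral = "neutral",
    surprise = "positive", contempt = "negative")
}

# Fine labels consistent with each latent state for generation purposes.
# Surprise and contempt belong to no cluster: they appear only as recognizer
# noise, matching the clustering rule that leaves them unassigned.
cluster_consistent_labels <- function() {
  list(
    negative = c("fear", "anger", "sadness", "disgust"),
    positive = "happiness",
    neutral  = "neutral"
  )
}

as_affect_factor <- function(x) factor(x, levels = affect_states())

as_fine_factor <- function(x) factor(x, levels = fine_emotions())
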