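#' The 16 emotion categories
#'
#' The label taxonomy used throughout the package: 16 discrete,
#' therapeutically relevant emotions, of which 4 carry negative valence
#' (anger, anxiety, disgust, sadness) and the remaining 12 positive valence.
#' Labels are returned in a fixed canonical order (alphabetical), which also
#' fixes the class order of every contingency matrix and classifier output.
#'
#' @return Character vector of the 16 emotion names in canonical order.
#' @export
#' @examples
#' emotion_labels()
#' emotion_valence("anger")
emotion_labels <- function() {
  c("anger", "anxiety", "confidence", "contentment", "courage", "disgust",
    "excitement", "gratitude", "happiness", "joy", "love", "pride",
    "relaxation", "resolve", "sadness", "tranquility")
}

.negative_emotions <- c("anger", "anxiety", "disgust", "sadness")

#' Valence of an emotion label
#'
#' Valence is a pure function of the label: anger, anxiety, disgust and
#' sadness are negative; the other 12 emotions are positive. This mapping
#' defines the binary (valence) classification task.
#'
#' @param label Character vector of emotion names (see [emotion_labels()]).
#' @return Character vector, each element `"negative"` or `"positive"`.
#' @export
emotion_valence <- function(label) {
  label <- as.character(label)
  bad <- setdiff(unique(label), emotion_labels())
  if (length(bad) > 0) {
    stop("unknown emotion label(s): ", paste(bad, collapse = ", "))
  }
  ifelse(label %in% .negative_emotions, "negative", "positive")
}

#' Levels of the valence factor
#' @return `c("negative", "positive")`.
#' @export
valence_levels <- function() c("negative", "positive")

# validate a vector of labels, returning it invisibly
.check_labels <- function(label) {
  invisible(emotion_valence(label))
}
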