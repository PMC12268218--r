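#' Published composition of the smartphone-video emotion study
#'
#' Summary counts of the smartphone-video emotion dataset the package is
#' designed for, as printed in its public description: per-emotion video
#' counts for the full dataset, video counts per partition, and per-emotion
#' video counts of the 3018-video test set annotated by human observers.
#' The raw videos are private; these counts are the public inputs from which
#' composition statistics (class shares, partition shares, chance levels)
#' are recomputed.
#'
#' @return A list with components:
#' \describe{
#'   \item{emotion_counts}{named integer vector, videos per emotion (full
#'     dataset).}
#'   \item{partition_counts}{named integer vector, videos in the training,
#'     validation and test partitions.}
#'   \item{partition_subjects}{named integer vector, subjects per partition.}
#'   \item{test_counts}{named integer vector, test-set videos per emotion.}
#'   \item{human_observers}{list: `n_raters`, and the human training set
#'     composition (`n_subjects`, `videos_per_emotion_per_subject`,
#'     `n_emotions`).}
#' }
#' @export
study_composition <- function() {
  lab <- emotion_labels()
  emotion_counts <- c(
    anger = 1691L, anxiety = 1620L, confidence = 645L, contentment = 635L,
    courage = 645L, disgust = 1635L, excitement = 645L, gratitude = 645L,
    happiness = 645L, joy = 669L, love = 670L, pride = 641L,
    relaxation = 612L, resolve = 636L, sadness = 1734L, tranquility = 645L
  )[lab]
  test_counts <- c(
    anger = 316L, anxiety = 534L, confidence = 145L, contentment = 135L,
    courage = 144L, disgust = 77L, excitement = 135L, gratitude = 144L,
    happiness = 135L, joy = 144L, love = 144L, pride = 145L,
    relaxation = 145L, resolve = 135L, sadness = 406L, tranquility = 134L
  )[lab]
  list(
    emotion_counts = emotion_counts,
    partition_counts = c(training = 8454L, validation = 2940L, test = 3018L),
    partition_subjects = c(training = 37L, validation = 13L, test = 13L),
    test_counts = test_counts,
    human_observers = list(
      n_raters = 3L,
      n_subjects = 3L,
      videos_per_emotion_per_subject = 3L,
      n_emotions = 16L
    )
  )
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves rounded up (away from zero),
#' matching the usual style of reported percentages, unlike base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Composition statistics recomputed from the printed counts
#'
#' Recomputes, from [study_composition()], the derived quantities reported
#' with the dataset: the per-emotion share of the full dataset, the share of
#' videos in each partition, the test-set total and per-emotion test-set
#' proportions, and the size of the human observers' training set
#' (subjects x emotions x videos per emotion per subject). Percentages are
#' rounded half-up to `digits` decimals.
#'
#' @param digits Decimal places for the percentage values (default 2, the
#'   precision used in the dataset tables).
#' @return A list with `dataset_share_pct`, `partition_share_pct`,
#'   `test_total`, `test_proportion_pct`, and `human_training_size`.
#' @export
#' @examples
#' comp <- composition_statistics()
#' comp$test_total            # 3018
#' comp$test_proportion_pct["anger"]  # 10.47
composition_statistics <- function(digits = 2) {
  comp <- study_composition()
  total <- sum(comp$partition_counts)  # authoritative dataset total
  test_total <- sum(comp$test_counts)
  h <- comp$human_observers
  list(
    dataset_share_pct = round_half_up(100 * comp$emotion_counts / total, digits),
    partition_share_pct = round_half_up(100 * comp$partition_counts / total, digits),
    test_total = test_total,
    test_proportion_pct = round_half_up(100 * comp$test_counts / test_total, digits),
    human_training_size = h$n_subjects * h$videos_per_emotion_per_subject * h$n_emotions
  )
}
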