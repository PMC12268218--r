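#' Video-level feature representation
#'
#' Collapses a per-frame appearance sequence to a single 35-vector by
#' averaging each feature over the time domain.
#'
#' @param seq An appearance `feature_sequence` (T >= 1).
#' @return Numeric vector of length 35.
#' @export
video_level_features <- function(seq) {
  stopifnot(inherits(seq, "feature_sequence"))
  if (nrow(seq$values) < 1) stop("empty feature sequence")
  colMeans(seq$values)
}

#' Leave-one-subject-out difficulty scores
#'
#' Measures how difficult each subject's videos are to classify: for every
#' subject, an RBF-kernel SVM (the package's baseline configuration) is
#' trained on all other subjects' video-level appearance features for the
#' 16-class task and evaluated on the held-out subject. The subject's score
#' is the resulting UAR; emotion classes absent from a subject's videos are
#' excluded from that subject's average. When records carry an audio
#' envelope, features are taken from the detected emotional phase, matching
#' the data path used for model training.
#'
#' @param corpus List of `video_record`s spanning at least 2 subjects and 2
#'   emotion classes.
#' @param segment Detect and trim to the emotional phase before averaging
#'   (default `TRUE`; requires envelopes).
#' @return Named numeric vector, one UAR per subject.
#' @export
loso_difficulty_scores <- function(corpus, segment = TRUE) {
  subjects <- corpus_subjects(corpus)
  labels <- corpus_labels(corpus)
  if (length(unique(subjects)) < 2) stop("need at least 2 subjects for LOSO scoring")
  if (length(unique(labels)) < 2) stop("need at least 2 emotion classes")
  if (segment && all(!vapply(corpus, function(r) is.null(r$envelope), logical(1)))) {
    corpus <- lapply(corpus, segment_record)
  }
  X <- t(vapply(corpus, function(r) video_level_features(r$features), numeric(35)))
  uniq <- sort(unique(subjects))
  scores <- vapply(uniq, function(s) {
    hold <- subjects == s
    model <- fit_svm_baseline(X[!hold, , drop = FALSE], labels[!hold])
    pred <- predict(model, X[hold, , drop = FALSE])
    A <- contingency(labels[hold], pred,
                     class_names = sort(unique(labels)))
    uar(A)  # rows without true instances are excluded inside uar()
  }, numeric(1))
  names(scores) <- uniq
  scores
}

#' Assign subjects to train/validation/test splits
#'
#' Subjects are sorted by difficulty score in descending order (ties broken
#' lexicographically by subject id) and assigned in a round-robin fashion
#' following the 5-slot pattern: 3 subjects to training, the 4th to
#' validation, the 5th to test, repeated until all subjects are assigned.
#' Two rules are available for the remainder when the subject count is not
#' a multiple of 5:
#' \describe{
#'   \item{`"strict"`}{continue the pattern from its start (remainder
#'     subjects go to training first). 63 subjects give 39/12/12.}
#'   \item{`"balanced"`}{distribute the remainder one per split in the order
#'     training, validation, test, spreading the lowest-scoring subjects
#'     across splits. 63 subjects give 37/13/13.}
#' }
#'
#' @param scores Named numeric vector of per-subject difficulty scores
#'   (higher = easier), e.g. from [loso_difficulty_scores()].
#' @param tail `"strict"` (default) or `"balanced"` remainder rule.
#' @return Named character vector mapping subject id to
#'   `"train"`, `"validation"` or `"test"`, of class `split_assignment`.
#' @export
assign_splits <- function(scores, tail = c("strict", "balanced")) {
  tail <- match.arg(tail)
  if (length(scores) < 1) stop("no subjects to assign")
  ord <- order(-scores, names(scores))
  ids <- names(scores)[ord]
  n <- length(ids)
  pattern <- c("train", "train", "train", "validation", "test")
  n_full <- (n %/% 5) * 5
  split <- character(n)
  if (n_full > 0) split[1:n_full] <- rep(pattern, n_full / 5)
  r <- n - n_full
  if (r > 0) {
    tail_pattern <- switch(tail,
      strict = pattern,
      balanced = c("train", "validation", "test", "train", "validation")
    )
    split[(n_full + 1):n] <- tail_pattern[seq_len(r)]
  }
  structure(stats::setNames(split, ids), class = "split_assignment")
}

#' Sizes of a split assignment
#' @param assignment A `split_assignment`.
#' @return Named integer vector with counts for train, validation, test.
#' @export
split_sizes <- function(assignment) {
  vapply(c("train", "validation", "test"),
         function(s) sum(assignment == s), integer(1))
}

#' Partition a corpus by a split assignment
#'
#' @param corpus List of `video_record`s.
#' @param assignment A `split_assignment` covering every subject in the
#'   corpus.
#' @return List with `train`, `validation` and `test` record lists.
#' @export
partition_corpus <- function(corpus, assignment) {
  subjects <- corpus_subjects(corpus)
  missing <- setdiff(unique(subjects), names(assignment))
  if (length(missing) > 0) {
    stop("subjects without a split assignment: ", paste(missing, collapse = ", "))
  }
  split <- unname(assignment[subjects])
  list(train = corpus[split == "train"],
       validation = corpus[split == "validation"],
       test = corpus[split == "test"])
}

#' Write / read a split assignment CSV
#'
#' @param assignment A `split_assignment`.
#' @param path CSV path (`subject_id,split`).
#' @return `path` (write) or a `split_assignment` (read).
#' @export
write_split <- function(assignment, path) {
  utils::write.csv(data.frame(subject_id = names(assignment),
                              split = unname(assignment)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(stats::setNames(df$split, df$subject_id), class = "split_assignment")
}
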