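# AU numbering used by the OpenFace feature set: 17 AUs carry both an
# intensity (0-5) and a presence (0/1) estimate; AU28 (lip suck) carries a
# presence estimate only, giving 17 + 18 = 35 appearance features per frame.
.au_intensity_numbers <- c(1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20, 23, 25, 26, 45)
.au_presence_numbers  <- c(1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20, 23, 25, 26, 28, 45)

.au_name <- function(n, suffix) sprintf("AU%02d_%s", n, suffix)

#' Canonical appearance feature names
#'
#' The 35 appearance features per frame in canonical column order: the 17 AU
#' intensity estimates (`AU01_r` ... `AU45_r`, ascending AU number) followed
#' by the 18 AU presence estimates (`AU01_c` ... `AU45_c`, including
#' `AU28_c`, ascending AU number). All appearance feature matrices in the
#' package use this order.
#'
#' @return Character vector of length 35.
#' @export
appearance_feature_names <- function() {
  c(.au_name(.au_intensity_numbers, "r"), .au_name(.au_presence_numbers, "c"))
}

.feature_dim <- function(kind) {
  switch(kind, appearance = 35L, deep = 2048L, concatenated = 2083L,
         stop("unknown feature kind: ", kind))
}

#' Construct a per-frame feature sequence
#'
#' A feature sequence is a T x D matrix of per-frame features at a fixed
#' frame rate, together with per-frame face-detection flags. D is fixed by
#' the feature kind: 35 for appearance (AU) features, 2048 for deep features,
#' 2083 for their concatenation (appearance columns first).
#'
#' @param values Numeric T x D matrix.
#' @param kind `"appearance"`, `"deep"` or `"concatenated"`.
#' @param fps Frame rate in frames per second (default 30).
#' @param detected Logical vector of length T; `TRUE` where a face was
#'   detected in the frame. Defaults to all `TRUE`.
#' @return An object of class `feature_sequence`.
#' @export
feature_sequence <- function(values, kind = c("appearance", "deep", "concatenated"),
                             fps = 30, detected = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) < 1) stop("feature sequence must contain at least one frame")
  if (ncol(values) != .feature_dim(kind)) {
    stop(sprintf("feature kind '%s' requires %d columns, got %d",
                 kind, .feature_dim(kind), ncol(values)))
  }
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (is.null(detected)) detected <- rep(TRUE, nrow(values))
  if (length(detected) != nrow(values)) {
    stop("detection flags must have one entry per frame")
  }
  if (kind == "appearance") .check_appearance_values(values)
  structure(
    list(values = unname(values), kind = kind, fps = fps,
         detected = as.logical(detected)),
    class = "feature_sequence"
  )
}

.check_appearance_values <- function(values) {
  intens <- values[, 1:17, drop = FALSE]
  pres <- values[, 18:35, drop = FALSE]
  if (any(intens < 0 | intens > 5)) {
    stop("AU intensities must lie in [0, 5]")
  }
  if (any(pres != 0 & pres != 1)) {
    stop("AU presences must be 0 or 1")
  }
  invisible(TRUE)
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> %d frames x %d features (%s), %g fps, %d undetected\n",
              nrow(x$values), ncol(x$values), x$kind, x$fps, sum(!x$detected)))
  invisible(x)
}

#' Number of frames in a feature sequence
#' @param seq A `feature_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) nrow(seq$values)

#' Read an OpenFace-style per-frame feature CSV
#'
#' Reads a comma-separated per-frame feature table in the OpenFace output
#' dialect: one row per video frame, a `success` column flagging whether a
#' face was detected, 17 AU intensity columns (`AU01_r` ... `AU45_r`) and 18
#' AU presence columns (`AU01_c` ... `AU45_c`, including `AU28_c`). Header
#' names may carry leading whitespace (as OpenFace writes them); names are
#' trimmed before matching. Columns are reordered into the canonical order of
#' [appearance_feature_names()]. A frame counts as detected when its
#' `success` value is at least 0.5; presence columns are read as numeric and
#' binarised at 0.5.
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate to record on the sequence (default 30).
#' @return An appearance [feature_sequence()].
#' @export
read_openface_features <- function(path, fps = 30) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty feature file: ", path)
  names(df) <- trimws(names(df))
  required <- c("success", appearance_feature_names())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("feature file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  values <- as.matrix(df[, appearance_feature_names(), drop = FALSE])
  storage.mode(values) <- "double"
  # binarise presences; intensities pass through
  values[, 18:35] <- as.numeric(values[, 18:35] >= 0.5)
  feature_sequence(values, kind = "appearance", fps = fps,
                   detected = df$success >= 0.5)
}

#' Write a feature sequence in the OpenFace CSV dialect
#'
#' Inverse of [read_openface_features()]: writes `frame`, `success` and the
#' 35 appearance columns. Round-trips values and detection flags exactly.
#'
#' @param seq An appearance `feature_sequence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_openface_features <- function(seq, path) {
  stopifnot(inherits(seq, "feature_sequence"))
  if (seq$kind != "appearance") stop("only appearance sequences use the OpenFace dialect")
  df <- data.frame(frame = seq_len(nrow(seq$values)) - 1L,
                   success = as.integer(seq$detected))
  mat <- as.data.frame(seq$values)
  names(mat) <- appearance_feature_names()
  utils::write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill face-detection gaps in a feature sequence
#'
#' Frames in which no face was detected are handled by carrying the last
#' detected frame's features forward until a new face appears; undetected
#' frames at the very beginning or end of the video are dropped. The result
#' has all detection flags `TRUE`.
#'
#' @param seq A `feature_sequence`.
#' @return A `feature_sequence` with gaps filled and edges trimmed.
#' @export
fill_face_gaps <- function(seq) {
  stopifnot(inherits(seq, "feature_sequence"))
  det <- seq$detected
  if (!any(det)) stop("no face detected in any frame")
  first <- which(det)[1]
  last <- which(det)[sum(det)]
  values <- seq$values[first:last, , drop = FALSE]
  det <- det[first:last]
  # carry last detected frame forward over internal gaps
  src <- cumsum(det)            # index (within detected frames) to copy from
  keep_rows <- which(det)
  values <- values[keep_rows[src], , drop = FALSE]
  feature_sequence(values, kind = seq$kind, fps = seq$fps,
                   detected = rep(TRUE, nrow(values)))
}

#' Concatenate appearance and deep feature sequences
#'
#' Joins an appearance (T x 35) and a deep (T x 2048) sequence frame-wise
#' into a concatenated T x 2083 sequence, appearance columns first. The two
#' inputs must be time-aligned: equal frame counts and equal frame rates.
#'
#' @param app Appearance `feature_sequence`.
#' @param deep Deep `feature_sequence`.
#' @return A `feature_sequence` of kind `"concatenated"`.
#' @export
concat_features <- function(app, deep) {
  stopifnot(inherits(app, "feature_sequence"), inherits(deep, "feature_sequence"))
  if (app$kind != "appearance" || deep$kind != "deep") {
    stop("concat_features expects an appearance and a deep sequence, in that order")
  }
  if (nrow(app$values) != nrow(deep$values)) {
    stop(sprintf("sequences are not aligned: %d vs %d frames",
                 nrow(app$values), nrow(deep$values)))
  }
  if (app$fps != deep$fps) stop("sequences are not aligned: frame rates differ")
  feature_sequence(cbind(app$values, deep$values), kind = "concatenated",
                   fps = app$fps, detected = app$detected & deep$detected)
}

#' Construct a video record
#'
#' A video record ties together the identity of the recorded subject, the
#' ground-truth emotion label, the per-frame feature sequence and, when
#' available, the per-frame audio energy envelope used for emotional-phase
#' detection and the true phase boundaries.
#'
#' Frame indices (phase boundaries, segments) are 0-based half-open
#' intervals `[start, end)` throughout the package.
#'
#' @param subject_id Subject identifier (string).
#' @param label Emotion label (one of [emotion_labels()]).
#' @param features A `feature_sequence`.
#' @param envelope Optional list with `values` (non-negative energy per
#'   audio frame) and `fps` (envelope frame rate).
#' @param phase Optional length-2 integer vector `c(start, end)`, the
#'   emotional phase as a 0-based half-open frame interval on the feature
#'   timeline.
#' @return An object of class `video_record`.
#' @export
video_record <- function(subject_id, label, features, envelope = NULL, phase = NULL) {
  .check_labels(label)
  stopifnot(inherits(features, "feature_sequence"))
  if (!is.null(envelope)) {
    if (any(envelope$values < 0)) stop("audio envelope values must be non-negative")
    if (envelope$fps <= 0) stop("envelope frame rate must be positive")
  }
  if (!is.null(phase)) {
    t_total <- nrow(features$values)
    if (length(phase) != 2 || phase[1] < 0 || phase[1] >= phase[2] || phase[2] > t_total) {
      stop("phase must satisfy 0 <= start < end <= T")
    }
  }
  structure(
    list(subject_id = as.character(subject_id), label = as.character(label),
         features = features, envelope = envelope, phase = phase),
    class = "video_record"
  )
}

#' @export
print.video_record <- function(x, ...) {
  cat(sprintf("<video_record> subject %s, label %s, %d frames%s\n",
              x$subject_id, x$label, nrow(x$features$values),
              if (is.null(x$phase)) "" else
                sprintf(", phase [%d, %d)", x$phase[1], x$phase[2])))
  invisible(x)
}

#' Read a corpus manifest
#'
#' A manifest is a CSV with columns `subject_id`, `emotion`, `feature_path`
#' and optionally `envelope_path`, one row per video. Paths are resolved
#' relative to the manifest's own directory.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with absolute paths.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "emotion", "feature_path")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  }
  .check_labels(df$emotion)
  base <- dirname(normalizePath(path))
  abspath <- function(p) ifelse(p == "" | is.na(p), NA_character_, file.path(base, p))
  df$feature_path <- abspath(df$feature_path)
  if ("envelope_path" %in% names(df)) df$envelope_path <- abspath(df$envelope_path)
  df
}

#' Read an audio energy envelope CSV
#'
#' One-column CSV whose header states the envelope frame rate as
#' `energy_<fps>hz` (e.g. `energy_30hz`).
#'
#' @param path Envelope CSV path.
#' @return List with `values` and `fps`.
#' @export
read_envelope <- function(path) {
  df <- utils::read.csv(path)
  header <- names(df)[1]
  m <- regmatches(header, regexec("^energy_([0-9.]+)hz$", header))[[1]]
  if (length(m) != 2) stop("envelope header must be of the form energy_<fps>hz, got: ", header)
  list(values = as.numeric(df[[1]]), fps = as.numeric(m[2]))
}

#' Write an audio energy envelope CSV
#' @param envelope List with `values` and `fps`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  df <- data.frame(x = envelope$values)
  names(df) <- sprintf("energy_%ghz", envelope$fps)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
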