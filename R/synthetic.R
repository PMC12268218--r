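# FACS-inspired AU loading table for the 16 emotion archetypes.
# Rows are the 17 intensity AUs in canonical order
# (1,2,4,5,6,7,9,10,12,14,15,17,20,23,25,26,45); entries are nominal
# intensities at separability 1. Negative emotions share brow-lowering /
# mouth-tension loadings (AU4, AU9, AU15, AU20), positive emotions share
# cheek-raise / lip-corner-pull loadings (AU6, AU12), so the valence split
# is wider than the within-valence class differences, as in posed
# expressions. Happiness carries its largest loadings on AU6 and AU12.
.archetype_table <- local({
  au <- c(1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20, 23, 25, 26, 45)
  set_au <- function(...) {
    spec <- c(...)
    v <- numeric(17)
    v[match(as.numeric(names(spec)), au)] <- spec
    v
  }
  tab <- rbind(
    anger       = set_au("4" = 2.2, "5" = 1.2, "7" = 1.5, "17" = 0.8, "23" = 1.8),
    anxiety     = set_au("1" = 1.8, "2" = 1.5, "4" = 1.4, "5" = 1.6, "20" = 1.8, "26" = 1.0),
    confidence  = set_au("2" = 0.6, "5" = 1.2, "7" = 0.8, "12" = 0.9, "23" = 0.8),
    contentment = set_au("6" = 0.8, "12" = 1.0, "25" = 0.4, "45" = 1.2),
    courage     = set_au("4" = 0.5, "5" = 1.4, "7" = 1.2, "12" = 0.7, "23" = 1.2),
    disgust     = set_au("4" = 1.0, "9" = 2.2, "10" = 1.6, "15" = 1.2, "17" = 1.0),
    excitement  = set_au("1" = 1.2, "2" = 1.4, "5" = 1.5, "12" = 1.6, "25" = 1.8, "26" = 1.2),
    gratitude   = set_au("1" = 1.0, "6" = 1.2, "12" = 1.6, "17" = 0.8, "25" = 0.9),
    happiness   = set_au("6" = 2.5, "12" = 2.4, "25" = 1.0),
    joy         = set_au("6" = 2.0, "12" = 2.0, "25" = 1.6, "26" = 1.4),
    love        = set_au("1" = 1.2, "6" = 1.6, "12" = 1.4, "25" = 0.8, "45" = 0.6),
    pride       = set_au("2" = 1.0, "5" = 0.8, "10" = 0.6, "12" = 1.2, "17" = 1.4),
    relaxation  = set_au("6" = 0.6, "12" = 0.6, "26" = 0.6, "45" = 1.5),
    resolve     = set_au("5" = 0.6, "7" = 1.0, "12" = 0.5, "17" = 1.2, "23" = 1.4),
    sadness     = set_au("1" = 2.0, "4" = 1.5, "15" = 2.0, "17" = 1.2),
    tranquility = set_au("1" = 0.4, "6" = 0.5, "12" = 0.4, "26" = 0.3, "45" = 1.0)
  )
  tab[emotion_labels(), , drop = FALSE]
})

# presence loadings: AUs with a strong intensity loading are "present";
# AU28 (presence only) marks lip suck for resolve and anxiety
.archetype_presence <- local({
  pres_au <- c(1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20, 23, 25, 26, 28, 45)
  int_au <- c(1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20, 23, 25, 26, 45)
  P <- matrix(0, nrow = 16, ncol = 18, dimnames = list(emotion_labels(), NULL))
  for (i in seq_len(16)) {
    strong <- int_au[.archetype_table[i, ] >= 0.8]
    P[i, match(strong, pres_au)] <- 0.8
  }
  P["resolve", match(28, pres_au)] <- 0.8
  P["anxiety", match(28, pres_au)] <- 0.8
  P
})

#' Appearance-feature archetype of an emotion
#'
#' Deterministic 35-dimensional mean appearance vector of an emotion label,
#' built from a fixed internal table of AU-emotion associations inspired by
#' FACS emotion coding. The archetype scales linearly with `separability`:
#' pairwise distances between distinct labels are proportional to it, and at
#' `separability = 0` all labels collapse onto the zero vector (features
#' carry no class information). Clipping of intensities to `[0, 5]` and
#' binarisation of presences happen at corpus sampling time, not here.
#'
#' @param label Emotion name (see [emotion_labels()]).
#' @param separability Non-negative scale factor (default 1).
#' @return Named numeric vector of length 35 in the order of
#'   [appearance_feature_names()].
#' @export
emotion_archetype <- function(label, separability = 1) {
  .check_labels(label)
  stopifnot(length(label) == 1, separability >= 0)
  v <- separability * c(.archetype_table[label, ], .archetype_presence[label, ])
  names(v) <- appearance_feature_names()
  v
}

#' Configuration of the synthetic corpus generator
#'
#' Defines a seeded synthetic corpus with the structural features of a
#' Wizard-of-Oz smartphone emotion study: a fixed roster of subjects; an
#' unequal number of videos per emotion (by default the negative emotions
#' have 2.5 times the videos of each positive emotion, mirroring the design
#' in which negative emotions recur daily); a three-phase timeline per video
#' (preparation, emotional phase, disengagement) at 30 fps; per-subject
#' appearance offsets; and per-frame noise.
#'
#' @param n_subjects Number of subjects (default 15).
#' @param per_emotion_counts Named integer vector of videos per emotion.
#'   Default: 15 per negative emotion, 6 per positive emotion.
#' @param separability Scale of the distance between emotion archetypes
#'   (default 1). 0 makes features class-uninformative.
#' @param subject_sd SD of the per-subject appearance offset (default 0.2).
#' @param noise_sd SD of the per-frame feature noise (default 0.3).
#' @param phase_durations Mean durations in seconds of the preparation,
#'   emotional and disengagement phases, `c(prep, emo, disengage)`.
#'   Defaults `c(1.0, 2.8, 1.0)`.
#' @param phase_jitter Half-width of the uniform jitter applied to each
#'   phase duration, same order. Defaults `c(0.3, 0.8, 0.3)`.
#' @param persist_s Seconds the facial expression persists beyond the end
#'   of the utterance (default 1).
#' @param fps Video frame rate (default 30).
#' @param env_fps Audio envelope frame rate (default 30).
#' @param include_deep Also synthesise 2048-dim deep features (default
#'   `FALSE`).
#' @param seed Integer seed; the corpus is a pure function of the
#'   configuration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 15,
                             per_emotion_counts = NULL,
                             separability = 1,
                             subject_sd = 0.2,
                             noise_sd = 0.3,
                             phase_durations = c(1.0, 2.8, 1.0),
                             phase_jitter = c(0.3, 0.8, 0.3),
                             persist_s = 1.0,
                             fps = 30,
                             env_fps = 30,
                             include_deep = FALSE,
                             seed = 1L) {
  if (is.null(per_emotion_counts)) {
    per_emotion_counts <- ifelse(emotion_valence(emotion_labels()) == "negative", 15L, 6L)
    names(per_emotion_counts) <- emotion_labels()
  }
  if (is.null(names(per_emotion_counts)) ||
      !setequal(names(per_emotion_counts), emotion_labels())) {
    stop("per_emotion_counts must be named with the 16 emotion labels")
  }
  per_emotion_counts <- per_emotion_counts[emotion_labels()]
  stopifnot(all(per_emotion_counts >= 0), separability >= 0, subject_sd >= 0,
            noise_sd >= 0, fps > 0, env_fps > 0, all(phase_durations > 0),
            all(phase_jitter >= 0), all(phase_jitter < phase_durations))
  structure(
    list(n_subjects = as.integer(n_subjects),
         per_emotion_counts = as.integer(per_emotion_counts) |>
           stats::setNames(emotion_labels()),
         separability = separability, subject_sd = subject_sd,
         noise_sd = noise_sd, phase_durations = phase_durations,
         phase_jitter = phase_jitter, persist_s = persist_s, fps = fps,
         env_fps = env_fps, include_deep = include_deep,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# fixed projection used to synthesise 2048-dim deep features from the 35
# appearance features; same map for every corpus
.deep_feature_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      map <<- withr_seed(874511L, matrix(stats::rnorm(2048 * 35, sd = 1 / sqrt(35)),
                                         nrow = 2048))
    }
    map
  }
})

#' Generate a synthetic video corpus
#'
#' Draws a corpus of [video_record()]s under `cfg`. Each video has three
#' concatenated phases (preparation, emotional, disengagement). During the
#' emotional phase the subject's appearance features follow the emotion
#' archetype modulated by a rise-sustain-decay temporal envelope (0.3 s
#' linear ramps), with the expression persisting `persist_s` seconds beyond
#' the utterance; outside the phase features sit near baseline. A
#' per-subject offset (SD `subject_sd`) is shared by all of a subject's
#' videos, and i.i.d. frame noise (SD `noise_sd`) is added throughout.
#' Intensities are clipped to `[0, 5]` and presences binarised at 0.5. The
#' audio envelope is high exactly during the utterance. The true emotional
#' phase (utterance plus `persist_s` of expression persistence, clipped to
#' the video length) is stored on each record.
#'
#' Per-emotion video counts match the configuration exactly, subjects are
#' rotated through emotions so that each subject records several emotions,
#' and the corpus is a pure function of `cfg` (same seed, same corpus).
#'
#' @param cfg A [synthetic_config()].
#' @return List of `video_record`s with attribute `"config"`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_subjects < 1 || all(cfg$per_emotion_counts == 0)) {
    stop("empty configuration: need at least one subject and one video")
  }
  withr_seed(cfg$seed, .generate_corpus_impl(cfg))
}

.generate_corpus_impl <- function(cfg) {
  labels <- emotion_labels()
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  offsets <- matrix(stats::rnorm(cfg$n_subjects * 35, sd = cfg$subject_sd),
                    nrow = cfg$n_subjects)
  deep_map <- if (cfg$include_deep) .deep_feature_map()
  records <- list()
  for (j in seq_along(labels)) {
    arch <- emotion_archetype(labels[j], cfg$separability)
    n_vid <- cfg$per_emotion_counts[j]
    if (n_vid == 0) next
    for (v in seq_len(n_vid)) {
      si <- ((v - 1 + (j - 1)) %% cfg$n_subjects) + 1
      rec <- .simulate_video(cfg, labels[j], subjects[si], arch, offsets[si, ],
                             deep_map)
      records[[length(records) + 1]] <- rec
    }
  }
  attr(records, "config") <- cfg
  records
}

.simulate_video <- function(cfg, label, subject, arch, offset, deep_map) {
  fps <- cfg$fps
  dur <- cfg$phase_durations +
    stats::runif(3, -cfg$phase_jitter, cfg$phase_jitter)
  n_prep <- max(1L, round(dur[1] * fps))
  n_emo <- max(1L, round(dur[2] * fps))
  n_dis <- max(1L, round(dur[3] * fps))
  t_total <- n_prep + n_emo + n_dis
  utt <- c(n_prep, n_prep + n_emo)  # utterance, 0-based half-open

  # expression envelope: ramps up 0.3 s at utterance onset, sustains through
  # the utterance and persist_s beyond it, ramps down 0.3 s, baseline 0.05
  ramp <- max(1L, round(0.3 * fps))
  persist <- round(cfg$persist_s * fps)
  tt <- seq_len(t_total) - 1L
  env <- rep(0.05, t_total)
  hi_start <- utt[1]
  hi_end <- min(t_total, utt[2] + persist)
  up <- tt >= hi_start & tt < hi_start + ramp
  env[up] <- 0.05 + 0.95 * (tt[up] - hi_start + 1) / ramp
  sustain <- tt >= hi_start + ramp & tt < hi_end
  env[sustain] <- 1
  down <- tt >= hi_end & tt < hi_end + ramp
  env[down] <- pmax(0.05, 1 - 0.95 * (tt[down] - hi_end + 1) / ramp)

  values <- env %o% arch +
    matrix(offset, nrow = t_total, ncol = 35, byrow = TRUE) +
    matrix(stats::rnorm(t_total * 35, sd = cfg$noise_sd), nrow = t_total)
  values[, 1:17] <- pmin(pmax(values[, 1:17], 0), 5)
  values[, 18:35] <- (values[, 18:35] > 0.5) * 1

  # audio: speech-band energy during the utterance only
  m_total <- max(1L, round(t_total / fps * cfg$env_fps))
  ts <- (seq_len(m_total) - 1L) / cfg$env_fps
  speech <- ts >= utt[1] / fps & ts < utt[2] / fps
  envelope_vals <- stats::runif(m_total, 0, 0.04)
  envelope_vals[speech] <- 0.65 + 0.3 * abs(sin(2 * pi * 4 * ts[speech])) +
    stats::runif(sum(speech), 0, 0.05)

  phase <- c(utt[1], min(t_total, utt[2] + persist))
  feats <- feature_sequence(values, kind = "appearance", fps = fps)
  rec <- video_record(subject, label, feats,
                      envelope = list(values = envelope_vals, fps = cfg$env_fps),
                      phase = phase)
  if (!is.null(deep_map)) {
    deep_vals <- values %*% t(deep_map) +
      matrix(stats::rnorm(t_total * 2048, sd = 0.1), nrow = t_total)
    rec$deep <- feature_sequence(deep_vals, kind = "deep", fps = fps)
  }
  rec
}

#' Labels and subjects of a corpus
#' @param corpus List of `video_record`s.
#' @return Character vector.
#' @export
corpus_labels <- function(corpus) vapply(corpus, function(r) r$label, character(1))

#' @rdname corpus_labels
#' @export
corpus_subjects <- function(corpus) vapply(corpus, function(r) r$subject_id, character(1))

#' Simulate human observer predictions on a corpus
#'
#' Generates per-video predicted labels for `n_raters` independent
#' observers: each rater labels each video correctly with probability
#' `accuracy_target`, and otherwise draws uniformly among the 15 wrong
#' labels. Used as a fixture for the agreement statistics.
#'
#' @param corpus List of `video_record`s.
#' @param accuracy_target Probability of a correct label, in `[0, 1]`.
#' @param n_raters Number of observers (default 3).
#' @param seed Integer seed.
#' @return Character matrix, videos in rows, raters in columns.
#' @export
generate_human_predictions <- function(corpus, accuracy_target, n_raters = 3,
                                       seed = 1L) {
  stopifnot(accuracy_target >= 0, accuracy_target <= 1, n_raters >= 1)
  truth <- corpus_labels(corpus)
  labels <- emotion_labels()
  withr_seed(seed, {
    preds <- matrix(NA_character_, nrow = length(truth), ncol = n_raters)
    for (r in seq_len(n_raters)) {
      correct <- stats::runif(length(truth)) < accuracy_target
      preds[, r] <- truth
      for (i in which(!correct)) {
        preds[i, r] <- sample(setdiff(labels, truth[i]), 1)
      }
    }
    colnames(preds) <- sprintf("rater%d", seq_len(n_raters))
    preds
  })
}

#' Write a corpus to disk in the package's file formats
#'
#' Writes one OpenFace-dialect feature CSV and one envelope CSV per record,
#' plus a `manifest.csv` tying them together.
#'
#' @param corpus List of `video_record`s (appearance features).
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(corpus), function(i) {
    rec <- corpus[[i]]
    fpath <- sprintf("video%04d_features.csv", i)
    write_openface_features(rec$features, file.path(dir, fpath))
    epath <- ""
    if (!is.null(rec$envelope)) {
      epath <- sprintf("video%04d_envelope.csv", i)
      write_envelope(rec$envelope, file.path(dir, epath))
    }
    data.frame(subject_id = rec$subject_id, emotion = rec$label,
               feature_path = fpath, envelope_path = epath)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return List of `video_record`s.
#' @export
read_corpus <- function(manifest_path) {
  manifest <- read_manifest(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    feats <- read_openface_features(manifest$feature_path[i])
    envl <- NULL
    if ("envelope_path" %in% names(manifest) && !is.na(manifest$envelope_path[i])) {
      envl <- read_envelope(manifest$envelope_path[i])
    }
    video_record(manifest$subject_id[i], manifest$emotion[i], feats,
                 envelope = envl)
  })
}
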