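# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default synthetic study corpus, segmented and partitioned
default_parts <- function() {
  cached("default_parts", {
    corpus <- generate_corpus(synthetic_config(seed = 3))
    segmented <- lapply(corpus, segment_record)
    scores <- loso_difficulty_scores(segmented, segment = FALSE)
    partition_corpus(segmented, assign_splits(scores))
  })
}

# a valid appearance matrix with values inside the AU ranges
random_appearance <- function(T_, seed = 1) {
  set.seed(seed)
  cbind(matrix(runif(T_ * 17, 0, 5), T_, 17),
        matrix(rbinom(T_ * 18, 1, 0.4), T_, 18))
}

# build a video record directly from an appearance matrix
make_record <- function(values, subject = "S01", label = "anger", fps = 30,
                        envelope = NULL, phase = NULL) {
  video_record(subject, label, feature_sequence(values, "appearance", fps = fps),
               envelope = envelope, phase = phase)
}

# write an OpenFace-dialect CSV with given AU values; `...` are
# column = value overrides applied after zero-filling
openface_csv <- function(n_rows, success = 1, overrides = list(),
                         drop_cols = character(0), pad_headers = FALSE) {
  cols <- appearance_feature_names()
  df <- as.data.frame(matrix(0, n_rows, length(cols)))
  names(df) <- cols
  for (nm in names(overrides)) {
    df[overrides[[nm]]$row, nm] <- overrides[[nm]]$value
  }
  df <- cbind(data.frame(frame = seq_len(n_rows) - 1, success = success), df)
  df <- df[, setdiff(names(df), drop_cols)]
  if (pad_headers) names(df) <- paste0(" ", names(df))
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
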