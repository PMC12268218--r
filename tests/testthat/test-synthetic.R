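test_that("archetype distances scale linearly with separability", {
  labs <- emotion_labels()
  for (pair in list(c("anger", "joy"), c("contentment", "tranquility"))) {
    d1 <- sqrt(sum((emotion_archetype(pair[1], 1) - emotion_archetype(pair[2], 1))^2))
    d2 <- sqrt(sum((emotion_archetype(pair[1], 2) - emotion_archetype(pair[2], 2))^2))
    expect_gt(d1, 0)
    expect_equal(d2, 2 * d1)
  }
  # degenerate case: separability 0 collapses all archetypes
  arch0 <- vapply(labs, emotion_archetype, numeric(35), separability = 0)
  expect_true(all(arch0 == 0))
})

test_that("all 16 archetypes are pairwise distinct at separability 1", {
  A <- vapply(emotion_labels(), emotion_archetype, numeric(35))
  d <- as.matrix(dist(t(A)))
  expect_true(all(d[upper.tri(d)] > 0.4))
})

test_that("the happiness archetype peaks on AU6 and AU12", {
  arch <- emotion_archetype("happiness")
  intens <- arch[1:17]
  top2 <- names(sort(intens, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("AU06_r", "AU12_r"))
})

test_that("corpus bookkeeping is exact and seeded", {
  counts <- stats::setNames(rep(2L, 16), emotion_labels())
  cfg <- synthetic_config(n_subjects = 2, per_emotion_counts = counts, seed = 9)
  corpus <- generate_corpus(cfg)
  expect_length(corpus, 32)
  expect_equal(as.vector(table(corpus_labels(corpus))), rep(2L, 16))
  expect_equal(sort(unique(corpus_subjects(corpus))), c("S01", "S02"))

  # bitwise determinism
  corpus2 <- generate_corpus(cfg)
  expect_identical(lapply(corpus, function(r) r$features$values),
                   lapply(corpus2, function(r) r$features$values))
  expect_identical(lapply(corpus, function(r) r$envelope$values),
                   lapply(corpus2, function(r) r$envelope$values))

  # different seed changes the draw
  corpus3 <- generate_corpus(synthetic_config(n_subjects = 2,
                                              per_emotion_counts = counts, seed = 10))
  expect_false(identical(corpus[[1]]$features$values, corpus3[[1]]$features$values))
})

test_that("default per-emotion counts carry the negative/positive imbalance", {
  cfg <- synthetic_config()
  neg <- emotion_valence(names(cfg$per_emotion_counts)) == "negative"
  expect_equal(unique(cfg$per_emotion_counts[neg] / cfg$per_emotion_counts[!neg]), 2.5)
})

test_that("degenerate configurations are rejected", {
  expect_error(generate_corpus(synthetic_config(n_subjects = 0)), "empty config")
  counts <- stats::setNames(rep(0L, 16), emotion_labels())
  expect_error(generate_corpus(synthetic_config(per_emotion_counts = counts)),
               "empty config")
})

test_that("audio energy is high only during the utterance", {
  cfg <- synthetic_config(n_subjects = 2,
                          per_emotion_counts = stats::setNames(rep(1L, 16),
                                                               emotion_labels()),
                          seed = 4)
  corpus <- generate_corpus(cfg)
  for (rec in corpus[1:5]) {
    env <- rec$envelope$values
    phase <- rec$phase
    # envelope timeline == feature timeline here (both 30 fps)
    utter_end <- phase[2] - round(cfg$persist_s * cfg$fps)
    inside <- env[(phase[1] + 1):utter_end]
    outside <- env[seq_len(phase[1])]
    expect_gt(min(inside), max(outside))
  }
})

test_that("phase boundaries are valid half-open frame intervals", {
  corpus <- generate_corpus(synthetic_config(seed = 8))
  for (rec in corpus) {
    expect_true(rec$phase[1] >= 0)
    expect_true(rec$phase[1] < rec$phase[2])
    expect_true(rec$phase[2] <= nrow(rec$features$values))
  }
})

test_that("a noise-free corpus is perfectly separable by nearest archetype", {
  counts <- stats::setNames(rep(2L, 16), emotion_labels())
  cfg <- synthetic_config(n_subjects = 4, per_emotion_counts = counts,
                          subject_sd = 0, noise_sd = 0, seed = 6)
  corpus <- generate_corpus(cfg)
  arch <- vapply(emotion_labels(), emotion_archetype, numeric(35))
  pred <- vapply(corpus, function(rec) {
    v <- video_level_features(segment_record(rec)$features)
    # compare directions: the temporal envelope scales the archetype
    sims <- apply(arch, 2, function(a) sum(v * a) / sqrt(sum(a^2)))
    names(which.max(sims))
  }, character(1))
  A <- contingency(corpus_labels(corpus), pred, emotion_labels())
  expect_equal(uar(A), 1)
})

test_that("separability 0 removes class information from the features", {
  counts <- stats::setNames(rep(4L, 16), emotion_labels())
  between_stat <- function(X, y) {
    overall <- colMeans(X)
    cls <- t(vapply(split(seq_len(nrow(X)), y),
                    function(i) colMeans(X[i, , drop = FALSE]), numeric(ncol(X))))
    mean(colMeans((cls - rep(overall, each = nrow(cls)))^2))
  }
  run <- function(sep) {
    cfg <- synthetic_config(n_subjects = 8, per_emotion_counts = counts,
                            separability = sep, seed = 12)
    corpus <- generate_corpus(cfg)
    X <- t(vapply(corpus, function(r) video_level_features(r$features), numeric(35)))
    y <- corpus_labels(corpus)
    s_obs <- between_stat(X, y)
    set.seed(17)
    s_perm <- vapply(1:200, function(b) between_stat(X, sample(y)), numeric(1))
    mean(s_perm >= s_obs)  # permutation p-value for class structure
  }
  # separability 0: the labels look exchangeable (no class signal)
  expect_gt(run(0), 0.05)
  # separability 1: class structure exceeds every permutation
  expect_lte(run(1), 1 / 201)
})

test_that("synthetic human raters hit their accuracy target", {
  counts <- stats::setNames(rep(4L, 16), emotion_labels())
  corpus <- generate_corpus(synthetic_config(n_subjects = 4,
                                             per_emotion_counts = counts, seed = 2))
  truth <- corpus_labels(corpus)

  perfect <- generate_human_predictions(corpus, accuracy_target = 1, seed = 1)
  expect_true(all(perfect == truth))
  expect_equal(fleiss_kappa(perfect), 1)

  # concentration around the target on many items
  big <- rep(list(corpus[[1]]), 3000)
  for (i in seq_along(big)) big[[i]]$label <- truth[(i %% 64) + 1]
  preds <- generate_human_predictions(big, accuracy_target = 0.9, n_raters = 1,
                                      seed = 5)
  acc <- mean(preds[, 1] == corpus_labels(big))
  expect_lt(abs(acc - 0.9), 0.02)

  # reproducibility
  again <- generate_human_predictions(corpus, accuracy_target = 0.5, seed = 7)
  expect_identical(again, generate_human_predictions(corpus, 0.5, seed = 7))
})

test_that("a corpus written to disk reads back equal", {
  counts <- stats::setNames(c(rep(1L, 4), rep(0L, 12)),
                            c("anger", "joy", "pride", "sadness",
                              setdiff(emotion_labels(),
                                      c("anger", "joy", "pride", "sadness"))))
  corpus <- generate_corpus(synthetic_config(n_subjects = 2,
                                             per_emotion_counts = counts, seed = 3))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  back <- read_corpus(file.path(dir, "manifest.csv"))
  expect_length(back, length(corpus))
  for (i in seq_along(corpus)) {
    expect_equal(back[[i]]$subject_id, corpus[[i]]$subject_id)
    expect_equal(back[[i]]$label, corpus[[i]]$label)
    expect_equal(back[[i]]$features$values, corpus[[i]]$features$values,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$envelope$values, corpus[[i]]$envelope$values,
                 tolerance = 1e-12)
  }
})

test_that("deep features are seeded linear images of the appearance stream", {
  counts <- stats::setNames(c(2L, rep(0L, 15)), emotion_labels())
  cfg <- synthetic_config(n_subjects = 1, per_emotion_counts = counts,
                          include_deep = TRUE, seed = 13)
  corpus <- generate_corpus(cfg)
  expect_equal(ncol(corpus[[1]]$deep$values), 2048)
  expect_equal(nrow(corpus[[1]]$deep$values), nrow(corpus[[1]]$features$values))
  # same seed, same deep draw
  corpus2 <- generate_corpus(cfg)
  expect_identical(corpus[[1]]$deep$values, corpus2[[1]]$deep$values)
})
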