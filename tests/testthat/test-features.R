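test_that("OpenFace CSVs are read into canonically ordered 35-column sequences", {
  # all-zero file
  seq0 <- read_openface_features(openface_csv(3))
  expect_equal(dim(seq0$values), c(3, 35))
  expect_true(all(seq0$values == 0))
  expect_true(all(seq0$detected))

  # a single nonzero entry lands in the right cell
  idx <- match("AU12_r", appearance_feature_names())
  seq1 <- read_openface_features(openface_csv(
    3, overrides = list(AU12_r = list(row = 2, value = 2.5))))
  expected <- matrix(0, 3, 35)
  expected[2, idx] <- 2.5
  expect_equal(seq1$values, expected)

  # leading whitespace in headers (OpenFace convention) is tolerated
  seq2 <- read_openface_features(openface_csv(
    2, overrides = list(AU06_r = list(row = 1, value = 1.25)), pad_headers = TRUE))
  expect_equal(seq2$values[1, match("AU06_r", appearance_feature_names())], 1.25)
})

test_that("missing columns and empty files are reported by name", {
  expect_error(read_openface_features(openface_csv(3, drop_cols = "AU28_c")),
               "AU28_c")
  expect_error(read_openface_features(openface_csv(2, drop_cols = "success")),
               "success")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("frame", "success", appearance_feature_names()), collapse = ","),
             empty)
  expect_error(read_openface_features(empty), "empty")
})

test_that("presence columns are binarised and success thresholded at 0.5", {
  path <- openface_csv(2, success = c(0.9, 0.3),
                       overrides = list(AU01_c = list(row = 1, value = 0.7)))
  seq <- read_openface_features(path)
  expect_equal(seq$detected, c(TRUE, FALSE))
  expect_equal(seq$values[1, match("AU01_c", appearance_feature_names())], 1)
})

test_that("write/read round-trips values and detection flags", {
  vals <- random_appearance(7, seed = 5)
  seq <- feature_sequence(vals, "appearance",
                          detected = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_openface_features(seq, path)
  back <- read_openface_features(path)
  expect_equal(back$values, seq$values)
  expect_equal(back$detected, seq$detected)
})

test_that("face gaps are filled by carrying the last detected frame", {
  a <- random_appearance(1, 1); b <- random_appearance(1, 2); c <- random_appearance(1, 3)
  seq <- feature_sequence(rbind(a, b, c), "appearance",
                          detected = c(TRUE, FALSE, TRUE))
  filled <- fill_face_gaps(seq)
  expect_equal(filled$values, rbind(a, a, c))
  expect_true(all(filled$detected))
})

test_that("undetected frames at the edges are dropped", {
  a <- random_appearance(1, 1); b <- random_appearance(1, 2); c <- random_appearance(1, 3)
  seq <- feature_sequence(rbind(a, b, c), "appearance",
                          detected = c(FALSE, TRUE, FALSE))
  expect_equal(fill_face_gaps(seq)$values, b)
})

test_that("gap filling is the identity on fully detected input and idempotent", {
  vals <- random_appearance(6, 9)
  seq <- feature_sequence(vals, "appearance")
  expect_equal(fill_face_gaps(seq)$values, vals)
  gappy <- feature_sequence(vals, "appearance",
                            detected = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  once <- fill_face_gaps(gappy)
  expect_equal(fill_face_gaps(once), once)
})

test_that("a sequence with no detected face is rejected", {
  seq <- feature_sequence(random_appearance(3), "appearance",
                          detected = rep(FALSE, 3))
  expect_error(fill_face_gaps(seq), "no face")
})

test_that("feature concatenation is dimension-exact and invertible", {
  app <- feature_sequence(random_appearance(2), "appearance")
  deep_vals <- matrix(rnorm(2 * 2048), 2, 2048)
  deep <- feature_sequence(deep_vals, "deep")
  both <- concat_features(app, deep)
  expect_equal(both$kind, "concatenated")
  expect_equal(dim(both$values), c(2, 2083))
  expect_equal(both$values[, 1:35], app$values)
  expect_equal(both$values[, 36:2083], deep_vals)

  deep3 <- feature_sequence(matrix(0, 3, 2048), "deep")
  expect_error(concat_features(app, deep3), "not aligned")
  expect_error(concat_features(deep, app), "appearance and a deep")
})

test_that("feature sequences enforce their dimensional invariants", {
  expect_error(feature_sequence(matrix(0, 2, 34), "appearance"), "35 columns")
  expect_error(feature_sequence(matrix(0, 2, 35), "deep"), "2048 columns")
  bad <- matrix(0, 2, 35); bad[1, 1] <- 6
  expect_error(feature_sequence(bad, "appearance"), "\\[0, 5\\]")
  bad2 <- matrix(0, 2, 35); bad2[1, 20] <- 0.5
  expect_error(feature_sequence(bad2, "appearance"), "0 or 1")
})

test_that("manifests and envelopes round-trip", {
  dir <- withr::local_tempdir()
  env <- list(values = c(0, 1.5, 2), fps = 25)
  write_envelope(env, file.path(dir, "e.csv"))
  back <- read_envelope(file.path(dir, "e.csv"))
  expect_equal(back$values, env$values)
  expect_equal(back$fps, 25)

  utils::write.csv(data.frame(subject_id = "S01", emotion = "joy",
                              feature_path = "f.csv", envelope_path = "e.csv"),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(basename(mf$feature_path), "f.csv")
  expect_error(read_manifest({
    p <- file.path(dir, "bad.csv")
    utils::write.csv(data.frame(subject_id = "S01"), p, row.names = FALSE)
    p
  }), "missing required")
})
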