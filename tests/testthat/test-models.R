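ns <- asNamespace("emoseq")

test_that("the SVM baseline separates well-separated Gaussian classes", {
  set.seed(21)
  X <- rbind(matrix(rnorm(100 * 35, mean = 0), ncol = 35),
             matrix(rnorm(100 * 35, mean = 3), ncol = 35))
  y <- rep(c("neg", "pos"), each = 100)
  fit <- fit_svm_baseline(X, y)
  pred <- predict(fit, X)
  expect_equal(uar(contingency(y, pred, c("neg", "pos"))), 1)
  # deterministic: same data, same predictions
  expect_identical(pred, predict(fit_svm_baseline(X, y), X))
})

test_that("the SVM rejects a single-class training set", {
  X <- matrix(rnorm(10 * 35), ncol = 35)
  expect_error(fit_svm_baseline(X, rep("joy", 10)), "one class")
})

test_that("SVM predictions on shuffled labels sit at chance on held-out data", {
  set.seed(33)
  X <- matrix(rnorm(300 * 35), ncol = 35)
  y <- sample(rep(c("a", "b"), each = 150))
  fit <- fit_svm_baseline(X[1:200, ], y[1:200])
  u <- uar(contingency(y[201:300], predict(fit, X[201:300, ]), c("a", "b")))
  expect_gt(u, 0.35)
  expect_lt(u, 0.65)
})

test_that("average pooling is the column mean", {
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(average_pool(H), colMeans(H))
  expect_equal(average_pool(H[1, , drop = FALSE]), H[1, ])
  Hc <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  expect_equal(average_pool(Hc), c(1, 2, 3))
})

test_that("attention pooling matches the literal two-loop formulas", {
  set.seed(41)
  for (rep_i in 1:5) {
    T_ <- sample(2:8, 1); h <- sample(2:6, 1); a <- sample(2:6, 1)
    H <- matrix(rnorm(T_ * h), T_, h)
    params <- list(W = matrix(rnorm(a * h), a, h), b = rnorm(a), c = rnorm(a))
    got <- attention_pool(H, params)
    want <- oracle_attention(H, params$W, params$b, params$c)
    expect_equal(got$pooled, want$pooled, tolerance = 1e-12)
    expect_equal(got$weights, want$weights, tolerance = 1e-12)
    expect_equal(sum(got$weights), 1)
  }
})

test_that("attention with zero parameters is exactly the average head", {
  set.seed(42)
  H <- matrix(rnorm(7 * 35), 7, 35)
  zero <- list(W = matrix(0, 35, 35), b = numeric(35), c = numeric(35))
  out <- attention_pool(H, zero)
  expect_identical(out$pooled, average_pool(H))
  expect_equal(out$weights, rep(1 / 7, 7))
  # single frame: weight 1, output is that frame
  out1 <- attention_pool(H[1, , drop = FALSE],
                         list(W = matrix(rnorm(35 * 35), 35, 35),
                              b = rnorm(35), c = rnorm(35)))
  expect_equal(out1$weights, 1)
  expect_equal(out1$pooled, H[1, ])
})

test_that("depthwise convolution pooling matches a sliding-window oracle", {
  set.seed(43)
  for (rep_i in 1:5) {
    T_ <- sample(1:9, 1); h <- sample(2:6, 1)
    H <- matrix(rnorm(T_ * h), T_, h)
    params <- list(kernel = matrix(rnorm(3 * h), 3, h), bias = rnorm(h))
    expect_equal(conv_pool(H, params), oracle_conv(H, params$kernel, params$bias),
                 tolerance = 1e-12)
  }
  # identity kernel: output is the time mean
  H <- matrix(rnorm(5 * 4), 5, 4)
  id <- list(kernel = rbind(0, 1, 0)[, rep(1, 4)], bias = numeric(4))
  expect_equal(conv_pool(H, id), colMeans(H))
  # single frame with kernel (a, b, c): zero padding leaves b * h1
  k <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(conv_pool(H[1, , drop = FALSE], list(kernel = k, bias = numeric(4))),
               k[2, ] * H[1, ])
})

test_that("analytic gradients match finite differences for every head", {
  set.seed(44)
  for (head in c("average", "attention", "convolution")) {
    modes <- if (head == "convolution") c("depthwise", "full") else "depthwise"
    for (mode in modes) {
      cfg <- model_config(task = "binary", head = head, gru_layers = 2,
                          gru_hidden = 4, mlp_hidden = c(5, 5),
                          conv_mode = mode, seed = 7)
      X <- matrix(rnorm(6 * 3), 6, 3)
      params <- ns$.init_params(cfg, 3)
      fwd <- ns$.net_forward(cfg, params, X)
      g <- ns$.flatten_params(ns$.net_backward(cfg, params, X, fwd, 2L))
      pflat <- ns$.flatten_params(params)
      eps <- 1e-6
      idx <- sample(seq_along(pflat), 40)  # spot-check a subset
      num <- vapply(idx, function(i) {
        pp <- pflat; pp[i] <- pp[i] + eps
        pm <- pflat; pm[i] <- pm[i] - eps
        lp <- -log(ns$.net_forward(cfg, ns$.unflatten_params(pp, params), X)$p[2])
        lm <- -log(ns$.net_forward(cfg, ns$.unflatten_params(pm, params), X)$p[2])
        (lp - lm) / (2 * eps)
      }, numeric(1))
      expect_equal(g[idx], num, tolerance = 1e-5,
                   info = paste(head, mode))
    }
  }
})

test_that("forward outputs live on the probability simplex and are deterministic", {
  cfg <- model_config(task = "multiclass", head = "attention", gru_layers = 2,
                      gru_hidden = 6, seed = 3)
  set.seed(9)
  params <- ns$.init_params(cfg, 35)
  X <- random_appearance(20)
  p1 <- ns$.net_forward(cfg, params, X)$p
  expect_length(p1, 16)
  expect_true(all(p1 >= 0))
  expect_equal(sum(p1), 1)
  expect_identical(p1, ns$.net_forward(cfg, params, X)$p)
  # constant sequences are invariant to frame permutation for every head
  Xc <- matrix(rep(random_appearance(1, 6), each = 10), 10, 35)
  for (head in c("average", "attention", "convolution")) {
    cfg_h <- model_config(task = "binary", head = head, gru_layers = 2,
                          gru_hidden = 6, seed = 3)
    set.seed(10)
    params_h <- ns$.init_params(cfg_h, 35)
    p_orig <- ns$.net_forward(cfg_h, params_h, Xc)$p
    p_perm <- ns$.net_forward(cfg_h, params_h, Xc[sample(10), ])$p
    expect_identical(p_orig, p_perm)
  }
})

test_that("the early-stopping rule reproduces hand-executed traces", {
  # improvement at epoch 2, then a plateau: stop after 3 stale epochs
  tr <- early_stop_trace(c(0.5, 0.6, 0.6, 0.6, 0.6, 0.6), patience = 3)
  expect_equal(tr$stop_epoch, 5)
  expect_equal(tr$best_epoch, 2)
  # monotone improvement never stops early
  tr2 <- early_stop_trace(seq(0.1, 0.9, by = 0.1), patience = 3)
  expect_equal(tr2$stop_epoch, 9)
  expect_equal(tr2$best_epoch, 9)
  # patience at least the history length runs everything
  tr3 <- early_stop_trace(c(0.9, 0.1, 0.1), patience = 3)
  expect_equal(tr3$stop_epoch, 3)
  expect_equal(tr3$best_epoch, 1)
  # ties do not count as improvement, and stopping fires before a late
  # recovery can be seen: best at 3, stale at 4 and 5, stop at 5
  tr4 <- early_stop_trace(c(0.3, 0.3, 0.4, 0.2, 0.2, 0.5, 0.5, 0.5), patience = 2)
  expect_equal(tr4$stop_epoch, 5)
  expect_equal(tr4$best_epoch, 3)
})

test_that("training honours the early-stopping semantics and the seed", {
  counts <- stats::setNames(rep(2L, 16), emotion_labels())
  cfg <- synthetic_config(n_subjects = 5, per_emotion_counts = counts, seed = 17)
  corpus <- generate_corpus(cfg)
  parts <- partition_corpus(corpus, assign_splits(
    stats::setNames(5:1 / 10, sprintf("S%02d", 1:5))))
  mcfg <- model_config(task = "binary", head = "average", max_epochs = 4,
                       patience = 10, seed = 5)
  fit <- train_model(parts$train, parts$validation, mcfg)
  # patience >= max_epochs: runs exactly max_epochs
  expect_equal(nrow(fit$history), 4)
  expect_lte(fit$best_epoch, 4)
  # the stopping rule applied to the recorded history matches the run
  tr <- early_stop_trace(fit$history$val_uar, mcfg$patience)
  expect_equal(fit$best_epoch, tr$best_epoch)
  # bitwise reproducibility
  fit2 <- train_model(parts$train, parts$validation, mcfg)
  expect_identical(predict(fit, parts$test, type = "prob"),
                   predict(fit2, parts$test, type = "prob"))
})

test_that("training rejects leaking or empty splits", {
  counts <- stats::setNames(rep(1L, 16), emotion_labels())
  corpus <- generate_corpus(synthetic_config(n_subjects = 4,
                                             per_emotion_counts = counts, seed = 2))
  mcfg <- model_config(task = "binary", max_epochs = 1)
  expect_error(train_model(corpus, corpus, mcfg), "leakage")
  expect_error(train_model(corpus, list(), mcfg), "empty")
})

test_that("model checkpoints round-trip through disk", {
  counts <- stats::setNames(rep(2L, 16), emotion_labels())
  corpus <- generate_corpus(synthetic_config(n_subjects = 5,
                                             per_emotion_counts = counts, seed = 19))
  parts <- partition_corpus(corpus, assign_splits(
    stats::setNames(5:1 / 10, sprintf("S%02d", 1:5))))
  fit <- train_model(parts$train, parts$validation,
                     model_config(task = "binary", head = "attention",
                                  max_epochs = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_equal(predict(back, parts$test, type = "prob"),
               predict(fit, parts$test, type = "prob"), tolerance = 1e-12)
  expect_equal(back$best_epoch, fit$best_epoch)
})

test_that("model_forward validates input dimensions", {
  counts <- stats::setNames(rep(2L, 16), emotion_labels())
  corpus <- generate_corpus(synthetic_config(n_subjects = 5,
                                             per_emotion_counts = counts, seed = 23))
  parts <- partition_corpus(corpus, assign_splits(
    stats::setNames(5:1 / 10, sprintf("S%02d", 1:5))))
  fit <- train_model(parts$train, parts$validation,
                     model_config(task = "binary", max_epochs = 1, seed = 5))
  expect_error(model_forward(fit, matrix(0, 4, 12)), "expects 35")
  p <- model_forward(fit, parts$test[[1]]$features)
  expect_equal(sum(p), 1)
  expect_named(p, valence_levels())
})
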