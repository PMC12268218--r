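# extract the T x D input matrix of a record for a given feature kind
.record_input <- function(rec, feature_kind) {
  switch(feature_kind,
    appearance = rec$features$values,
    deep = {
      if (is.null(rec$deep)) stop("record has no deep features")
      rec$deep$values
    },
    concatenated = {
      if (is.null(rec$deep)) stop("record has no deep features to concatenate")
      cbind(rec$features$values, rec$deep$values)
    })
}

#' Train a GRU sequence classifier
#'
#' Trains the configured GRU + pooling head + MLP classifier with Adam and
#' cross-entropy loss on the training records, monitoring UAR on the
#' validation records after every epoch. Training stops when the validation
#' UAR has not improved for `patience` consecutive epochs or when
#' `max_epochs` is reached; the returned model carries the weights of the
#' best epoch. Inputs are z-scored per feature with statistics estimated
#' from the training split. Sequences are processed at their native
#' lengths; a minibatch averages the per-sequence gradients. The training
#' and validation splits must be subject-disjoint.
#'
#' @param train,val Lists of `video_record`s (e.g. from
#'   [partition_corpus()]), non-empty and subject-disjoint.
#' @param cfg A [model_config()].
#' @param verbose Print per-epoch progress (default `FALSE`).
#' @return A fitted model of class `gru_model`: `config`, `params` (best
#'   epoch weights), `standardizer`, `classes`, `history` (per-epoch
#'   training loss and validation UAR) and `best_epoch`.
#' @export
train_model <- function(train, val, cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "model_config"))
  if (length(train) == 0 || length(val) == 0) stop("empty training or validation split")
  overlap <- intersect(unique(corpus_subjects(train)), unique(corpus_subjects(val)))
  if (length(overlap) > 0) {
    stop("subject leakage between train and validation: ",
         paste(overlap, collapse = ", "))
  }
  classes <- .task_classes(cfg$task)
  y_train <- match(.task_targets(cfg$task, corpus_labels(train)), classes)
  y_val <- .task_targets(cfg$task, corpus_labels(val))

  X_train <- lapply(train, .record_input, feature_kind = cfg$feature_kind)
  X_val <- lapply(val, .record_input, feature_kind = cfg$feature_kind)
  std <- fit_standardizer(do.call(rbind, X_train))
  X_train <- lapply(X_train, function(X) apply_standardizer(std, X))
  X_val <- lapply(X_val, function(X) apply_standardizer(std, X))

  withr_seed(cfg$seed, {
    params <- .init_params(cfg, ncol(X_train[[1]]))
    skeleton <- params
    adam <- list(t = 0, m = .zero_like(params), v = .zero_like(params))
    n_train <- length(X_train)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_uar = numeric())
    best_uar <- -Inf
    best_epoch <- 0L
    best_params <- params
    for (epoch in seq_len(cfg$max_epochs)) {
      order_idx <- sample.int(n_train)
      batches <- split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        grad_flat <- numeric(length(adam$m))
        for (i in batch) {
          fwd <- .net_forward(cfg, params, X_train[[i]])
          epoch_loss <- epoch_loss - log(max(fwd$p[y_train[i]], 1e-12))
          g <- .net_backward(cfg, params, X_train[[i]], fwd, y_train[i])
          grad_flat <- grad_flat + .flatten_params(g)
        }
        grad_flat <- grad_flat / length(batch)
        adam <- .adam_step(adam, grad_flat, cfg$learning_rate)
        params <- .unflatten_params(.flatten_params(params) + adam$delta, skeleton)
      }
      pred_val <- vapply(X_val, function(X) {
        classes[which.max(.net_forward(cfg, params, X)$p)]
      }, character(1))
      val_uar <- uar(contingency(y_val, pred_val, classes))
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = epoch_loss / n_train,
                                           val_uar = val_uar))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val UAR %.3f",
                        epoch, epoch_loss / n_train, val_uar))
      }
      if (val_uar > best_uar) {
        best_uar <- val_uar
        best_epoch <- epoch
        best_params <- params
      }
      if (epoch - best_epoch >= cfg$patience) break
    }
    structure(
      list(config = cfg, params = best_params, standardizer = std,
           classes = classes, history = history, best_epoch = best_epoch),
      class = "gru_model"
    )
  })
}

#' Class probabilities for one feature sequence
#'
#' Runs a trained model on a single sequence: the input is standardised
#' with the model's training-split statistics, passed through the GRU, the
#' pooling head and the MLP, and the softmax output returned.
#'
#' @param model A `gru_model`.
#' @param seq A `feature_sequence` (or bare T x D matrix) of the feature
#'   kind the model was trained on.
#' @return Named probability vector over the model's classes (non-negative,
#'   sums to 1).
#' @export
model_forward <- function(model, seq) {
  stopifnot(inherits(model, "gru_model"))
  X <- if (inherits(seq, "feature_sequence")) seq$values else as.matrix(seq)
  if (ncol(X) != length(model$standardizer$mean)) {
    stop(sprintf("input has %d features but the model expects %d",
                 ncol(X), length(model$standardizer$mean)))
  }
  Xstd <- apply_standardizer(model$standardizer, X)
  p <- .net_forward(model$config, model$params, Xstd)$p
  stats::setNames(p, model$classes)
}

#' Predict labels for a list of records
#'
#' @param object A `gru_model`.
#' @param newdata List of `video_record`s, or a single `feature_sequence`.
#' @param type `"label"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of predicted labels, or a probability matrix.
#' @export
predict.gru_model <- function(object, newdata, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_sequence") || is.matrix(newdata)) {
    newdata <- list(list(features = newdata))
    probs <- matrix(model_forward(object, newdata[[1]]$features), nrow = 1)
  } else {
    probs <- t(vapply(newdata, function(rec) {
      model_forward(object, .record_input(rec, object$config$feature_kind))
    }, numeric(length(object$classes))))
  }
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.gru_model <- function(x, ...) {
  cat(sprintf("<gru_model> %s task, %s head, %s features; best epoch %d/%d (val UAR %.3f)\n",
              x$config$task, x$config$head, x$config$feature_kind,
              x$best_epoch, nrow(x$history),
              max(x$history$val_uar)))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' Stores the configuration, standardiser, weights and training history in
#' a single JSON file (weights flattened; exact to double precision via
#' base-64-free decimal serialisation).
#'
#' @param model A `gru_model`.
#' @param path Output file path.
#' @return `path` (save) or a `gru_model` (load).
#' @export
save_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    classes = model$classes,
    standardizer = list(mean = model$standardizer$mean, sd = model$standardizer$sd),
    flat_params = .flatten_params(model$params),
    history = model$history,
    best_epoch = model$best_epoch,
    input_dim = length(model$standardizer$mean)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, payload$config[setdiff(names(payload$config), NULL)])
  skeleton <- withr_seed(cfg$seed, .init_params(cfg, payload$input_dim))
  structure(
    list(config = cfg,
         params = .unflatten_params(payload$flat_params, skeleton),
         standardizer = structure(list(mean = payload$standardizer$mean,
                                       sd = payload$standardizer$sd),
                                  class = "standardizer"),
         classes = payload$classes,
         history = as.data.frame(payload$history),
         best_epoch = payload$best_epoch),
    class = "gru_model"
  )
}
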