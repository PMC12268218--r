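#' Model configuration
#'
#' Hyperparameters of the GRU sequence classifiers: a 1-directional stacked
#' GRU (3 layers, hidden size 35) feeding one of three pooling heads
#' (average, attention, convolution), followed by an MLP with two 24-unit
#' ReLU hidden layers and a softmax output. Trained with Adam (learning
#' rate 0.001), batch size 64, cross-entropy loss and early stopping on
#' validation UAR with a patience of 30 epochs.
#'
#' @param task `"binary"` (valence, 2 outputs) or `"multiclass"` (16
#'   emotions).
#' @param head `"average"`, `"attention"` or `"convolution"`.
#' @param feature_kind `"appearance"`, `"deep"` or `"concatenated"`.
#' @param gru_layers Number of stacked GRU layers (default 3).
#' @param gru_hidden GRU hidden size (default 35); also the attention
#'   context dimension.
#' @param mlp_hidden Sizes of the two MLP hidden layers (default
#'   `c(24, 24)`).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 64).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param max_epochs Maximum number of training epochs (default 500).
#' @param conv_mode `"depthwise"` (default; the kernel slides over
#'   consecutive frames of the same feature) or `"full"` (full-channel
#'   kernel).
#' @param seed Integer seed controlling initialisation and batch order.
#' @return A list of class `model_config`.
#' @export
model_config <- function(task = c("multiclass", "binary"),
                         head = c("attention", "average", "convolution"),
                         feature_kind = c("appearance", "deep", "concatenated"),
                         gru_layers = 3, gru_hidden = 35, mlp_hidden = c(24, 24),
                         learning_rate = 0.001, batch_size = 64, patience = 30,
                         max_epochs = 500, conv_mode = c("depthwise", "full"),
                         seed = 1L) {
  task <- match.arg(task)
  head <- match.arg(head)
  feature_kind <- match.arg(feature_kind)
  conv_mode <- match.arg(conv_mode)
  stopifnot(gru_layers >= 1, gru_hidden >= 1, length(mlp_hidden) == 2,
            patience >= 1, max_epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(
    list(task = task, head = head, feature_kind = feature_kind,
         gru_layers = as.integer(gru_layers), gru_hidden = as.integer(gru_hidden),
         mlp_hidden = as.integer(mlp_hidden), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         max_epochs = as.integer(max_epochs), conv_mode = conv_mode,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

.task_classes <- function(task) {
  if (task == "binary") valence_levels() else emotion_labels()
}

.task_targets <- function(task, labels) {
  if (task == "binary") emotion_valence(labels) else labels
}

# uniform(-1/sqrt(h), 1/sqrt(h)) initialisation, the standard for GRU weights
.init_gru_layer <- function(d, h) {
  k <- 1 / sqrt(h)
  list(Wx = matrix(stats::runif(3 * h * d, -k, k), 3 * h, d),
       Wh = matrix(stats::runif(3 * h * h, -k, k), 3 * h, h),
       bx = stats::runif(3 * h, -k, k),
       bh = stats::runif(3 * h, -k, k))
}

.init_head <- function(cfg) {
  h <- cfg$gru_hidden
  k <- 1 / sqrt(h)
  switch(cfg$head,
    average = list(),
    attention = list(W = matrix(stats::runif(h * h, -k, k), h, h),
                     b = stats::runif(h, -k, k),
                     c = stats::runif(h, -k, k)),
    convolution = {
      if (cfg$conv_mode == "depthwise") {
        list(kernel = matrix(stats::runif(3 * h, -1 / sqrt(3), 1 / sqrt(3)), 3, h),
             bias = numeric(h))
      } else {
        kk <- 1 / sqrt(3 * h)
        list(kernel = array(stats::runif(3 * h * h, -kk, kk), c(3, h, h)),
             bias = numeric(h))
      }
    })
}

.init_mlp <- function(h, hidden, K) {
  he <- function(nin, nout) matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
  list(W1 = he(h, hidden[1]), b1 = numeric(hidden[1]),
       W2 = he(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
       W3 = he(hidden[2], K), b3 = numeric(K))
}

.init_params <- function(cfg, input_dim) {
  h <- cfg$gru_hidden
  layers <- vector("list", cfg$gru_layers)
  d <- input_dim
  for (l in seq_len(cfg$gru_layers)) {
    layers[[l]] <- .init_gru_layer(d, h)
    d <- h
  }
  list(gru = layers, head = .init_head(cfg),
       mlp = .init_mlp(h, cfg$mlp_hidden, length(.task_classes(cfg$task))))
}

# full-channel convolution head (optional variant)
.conv_full_forward <- function(H, params) {
  T_ <- nrow(H); h <- ncol(H)
  zero <- matrix(0, 1, h)
  Hm1 <- rbind(zero, H[-T_, , drop = FALSE])
  Hp1 <- rbind(H[-1, , drop = FALSE], zero)
  Y <- Hm1 %*% t(params$kernel[1, , ]) + H %*% t(params$kernel[2, , ]) +
       Hp1 %*% t(params$kernel[3, , ])
  Y <- sweep(Y, 2, params$bias, "+")
  colMeans(Y)
}

.conv_full_backward <- function(H, params, dv) {
  T_ <- nrow(H); h <- ncol(H)
  zero <- matrix(0, 1, h)
  Hm1 <- rbind(zero, H[-T_, , drop = FALSE])
  Hp1 <- rbind(H[-1, , drop = FALSE], zero)
  dY <- matrix(dv / T_, T_, h, byrow = TRUE)
  dk <- array(0, c(3, h, h))
  dk[1, , ] <- t(dY) %*% Hm1
  dk[2, , ] <- t(dY) %*% H
  dk[3, , ] <- t(dY) %*% Hp1
  dH <- dY %*% params$kernel[2, , ]
  dH[-T_, ] <- dH[-T_, , drop = FALSE] + dY[-1, , drop = FALSE] %*% params$kernel[1, , ]
  dH[-1, ] <- dH[-1, , drop = FALSE] + dY[-T_, , drop = FALSE] %*% params$kernel[3, , ]
  list(dH = dH, grads = list(kernel = dk, bias = colSums(dY)))
}

.head_forward <- function(cfg, H, head_params) {
  switch(cfg$head,
    average = list(v = average_pool(H)),
    attention = {
      out <- attention_pool(H, head_params)
      list(v = out$pooled, weights = out$weights)
    },
    convolution = {
      v <- if (cfg$conv_mode == "depthwise") conv_pool(H, head_params)
           else .conv_full_forward(H, head_params)
      list(v = v)
    })
}

.head_backward <- function(cfg, H, head_params, dv) {
  switch(cfg$head,
    average = list(dH = matrix(dv / nrow(H), nrow(H), length(dv), byrow = TRUE),
                   grads = list()),
    attention = .attention_backward(H, head_params, dv),
    convolution = if (cfg$conv_mode == "depthwise") {
      .conv_backward(H, head_params, dv)
    } else {
      .conv_full_backward(H, head_params, dv)
    })
}

# full forward pass on one (already standardised) T x D matrix
.net_forward <- function(cfg, params, Xstd) {
  fw <- .gru_forward_cpp(Xstd, params$gru)
  Htop <- fw$H[[cfg$gru_layers]]
  hd <- .head_forward(cfg, Htop, params$head)
  mlp <- .mlp_forward(hd$v, params$mlp)
  list(p = mlp$p, gru = fw, Htop = Htop, head = hd, mlp_cache = mlp)
}

# gradients of the cross-entropy loss for one sequence; y is the class index
.net_backward <- function(cfg, params, Xstd, fwd, y_index) {
  dlogits <- fwd$p
  dlogits[y_index] <- dlogits[y_index] - 1
  mb <- .mlp_backward(fwd$mlp_cache, params$mlp, dlogits)
  hb <- .head_backward(cfg, fwd$Htop, params$head, mb$dv)
  gb <- .gru_backward_cpp(Xstd, params$gru, fwd$gru, hb$dH)
  list(gru = gb$layers, head = hb$grads, mlp = mb$grads)
}

# ---- parameter flattening for the Adam update -----------------------------

.flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

.unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    if (n == 0L) return(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(out) <- dim(x)
    out
  }
  fill(skeleton)
}

.zero_like <- function(p) {
  flat <- .flatten_params(p)
  numeric(length(flat))
}

.adam_step <- function(state, grad_flat, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad_flat
  state$v <- beta2 * state$v + (1 - beta2) * grad_flat^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Early-stopping trace
#'
#' Applies the early-stopping rule to a per-epoch validation metric
#' history: the best epoch is the earliest epoch attaining the maximum so
#' far (strict improvement required to move it), and training stops after
#' the first epoch lying `patience` epochs beyond the best one.
#'
#' @param history Numeric vector of per-epoch validation metric values.
#' @param patience Number of epochs without improvement tolerated.
#' @return List with `stop_epoch` (last epoch run) and `best_epoch`.
#' @export
early_stop_trace <- function(history, patience) {
  stopifnot(length(history) >= 1, patience >= 1)
  best <- 1
  for (e in seq_along(history)) {
    if (history[e] > history[best]) best <- e
    if (e - best >= patience) {
      return(list(stop_epoch = e, best_epoch = best))
    }
  }
  list(stop_epoch = length(history), best_epoch = best)
}
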