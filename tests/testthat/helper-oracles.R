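# Independent brute-force oracles, written as literal loops over items and
# classes so they share no code with the package implementations.

oracle_contingency <- function(truth, pred, classes) {
  K <- length(classes)
  A <- matrix(0L, K, K, dimnames = list(classes, classes))
  for (i in seq_along(truth)) {
    A[match(truth[i], classes), match(pred[i], classes)] <-
      A[match(truth[i], classes), match(pred[i], classes)] + 1L
  }
  A
}

oracle_uar <- function(truth, pred, classes) {
  recalls <- c()
  for (k in classes) {
    idx <- which(truth == k)
    if (length(idx) == 0) next
    recalls <- c(recalls, sum(pred[idx] == k) / length(idx))
  }
  sum(recalls) / length(recalls)
}

oracle_accuracy <- function(truth, pred) {
  n_ok <- 0
  for (i in seq_along(truth)) if (truth[i] == pred[i]) n_ok <- n_ok + 1
  n_ok / length(truth)
}

oracle_balanced_accuracy <- function(truth, pred, classes) {
  out <- numeric(0)
  for (k in classes) {
    pos <- which(truth == k)
    neg <- which(truth != k)
    sens <- if (length(pos) > 0) sum(pred[pos] == k) / length(pos) else NA
    spec <- if (length(neg) > 0) sum(pred[neg] != k) / length(neg) else NA
    out[k] <- mean(c(sens, spec), na.rm = TRUE)
  }
  out
}

oracle_cohen_kappa <- function(r1, r2) {
  cats <- sort(unique(c(r1, r2)))
  n <- length(r1)
  po <- sum(r1 == r2) / n
  pe <- 0
  for (k in cats) {
    pe <- pe + (sum(r1 == k) / n) * (sum(r2 == k) / n)
  }
  (po - pe) / (1 - pe)
}

# literal two-loop evaluation of the context-attention formulas
oracle_attention <- function(H, W, b, cvec) {
  T_ <- nrow(H)
  s <- numeric(T_)
  for (t in seq_len(T_)) {
    u_t <- tanh(W %*% H[t, ] + b)
    s[t] <- sum(u_t * cvec)
  }
  alpha <- exp(s - max(s))
  alpha <- alpha / sum(alpha)
  v <- numeric(ncol(H))
  for (t in seq_len(T_)) v <- v + alpha[t] * H[t, ]
  list(pooled = v, weights = alpha)
}

# explicit sliding-window depthwise convolution, zero padded, then time mean
oracle_conv <- function(H, kernel, bias) {
  T_ <- nrow(H)
  h <- ncol(H)
  v <- numeric(h)
  for (cdim in seq_len(h)) {
    ys <- numeric(T_)
    for (t in seq_len(T_)) {
      acc <- bias[cdim]
      for (j in -1:1) {
        tj <- t + j
        xj <- if (tj >= 1 && tj <= T_) H[tj, cdim] else 0
        acc <- acc + kernel[j + 2, cdim] * xj
      }
      ys[t] <- acc
    }
    v[cdim] <- mean(ys)
  }
  v
}
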