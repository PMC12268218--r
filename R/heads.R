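#' Average pooling head
#'
#' Reduces a T x h hidden-state matrix to an h-vector by averaging each
#' dimension over time. Computed as `H' w` with uniform weights `w = 1/T`,
#' so that [attention_pool()] with all-zero parameters (uniform attention)
#' reproduces it bit for bit.
#'
#' @param H Numeric T x h matrix.
#' @return Numeric h-vector.
#' @export
average_pool <- function(H) {
  H <- as.matrix(H)
  stopifnot(nrow(H) >= 1)
  as.vector(crossprod(H, rep(1 / nrow(H), nrow(H))))
}

#' Attention pooling head
#'
#' Learned-context attention over frames: each hidden state is projected
#' through `u_t = tanh(W h_t + b)`, scored against a context vector c by
#' `s_t = u_t' c`, and the scores are softmax-normalised over time into
#' attention weights `alpha`. The pooled representation is the
#' alpha-weighted sum of the hidden states. With `W`, `b`, `c` all zero the
#' weights are uniform and the head equals [average_pool()].
#'
#' @param H Numeric T x h matrix.
#' @param params List with `W` (a x h), `b` (a), `c` (a); the context
#'   dimension a defaults to h in trained models.
#' @return List with `pooled` (h-vector) and `weights` (length-T attention
#'   weights summing to 1).
#' @export
attention_pool <- function(H, params) {
  H <- as.matrix(H)
  stopifnot(nrow(H) >= 1)
  U <- tanh(H %*% t(params$W) + matrix(params$b, nrow(H), length(params$b), byrow = TRUE))
  s <- as.vector(U %*% params$c)
  s <- s - max(s)  # softmax, stabilised
  alpha <- exp(s) / sum(exp(s))
  list(pooled = as.vector(crossprod(H, alpha)), weights = alpha)
}

# gradients of the attention head; dv is the h-vector gradient of the loss
# wrt the pooled output
.attention_backward <- function(H, params, dv) {
  T_ <- nrow(H)
  U <- tanh(H %*% t(params$W) + matrix(params$b, T_, length(params$b), byrow = TRUE))
  s <- as.vector(U %*% params$c)
  s <- s - max(s)
  alpha <- exp(s) / sum(exp(s))
  dalpha <- as.vector(H %*% dv)
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  dU <- outer(ds, params$c)
  dA <- dU * (1 - U^2)
  dH <- outer(alpha, dv) + dA %*% params$W
  list(dH = dH,
       grads = list(W = t(dA) %*% H, b = colSums(dA), c = as.vector(t(U) %*% ds)))
}

#' Depthwise convolution pooling head
#'
#' Applies a 1-D convolution of kernel size 3, stride 1 and same (zero)
#' padding independently to each hidden dimension over time — the kernel
#' slides over consecutive frames of the *same* feature — followed by
#' adaptive average pooling to a single value per dimension.
#'
#' @param H Numeric T x h matrix.
#' @param params List with `kernel` (3 x h matrix; rows are the weights for
#'   frames t-1, t, t+1) and `bias` (h-vector).
#' @return Numeric h-vector.
#' @export
conv_pool <- function(H, params) {
  H <- as.matrix(H)
  T_ <- nrow(H)
  stopifnot(T_ >= 1, nrow(params$kernel) == 3, ncol(params$kernel) == ncol(H))
  zero <- matrix(0, 1, ncol(H))
  Hm1 <- rbind(zero, H[-T_, , drop = FALSE])      # frame t-1 (zero padded)
  Hp1 <- rbind(H[-1, , drop = FALSE], zero)       # frame t+1 (zero padded)
  Y <- sweep(Hm1, 2, params$kernel[1, ], "*") +
       sweep(H,   2, params$kernel[2, ], "*") +
       sweep(Hp1, 2, params$kernel[3, ], "*")
  Y <- sweep(Y, 2, params$bias, "+")
  colMeans(Y)
}

.conv_backward <- function(H, params, dv) {
  T_ <- nrow(H)
  zero <- matrix(0, 1, ncol(H))
  Hm1 <- rbind(zero, H[-T_, , drop = FALSE])
  Hp1 <- rbind(H[-1, , drop = FALSE], zero)
  dY <- matrix(dv / T_, T_, ncol(H), byrow = TRUE)
  dk <- rbind(colSums(dY * Hm1), colSums(dY * H), colSums(dY * Hp1))
  dbias <- colSums(dY)
  dH <- sweep(dY, 2, params$kernel[2, ], "*")
  dH[-T_, ] <- dH[-T_, , drop = FALSE] +
    sweep(dY[-1, , drop = FALSE], 2, params$kernel[1, ], "*")
  dH[-1, ] <- dH[-1, , drop = FALSE] +
    sweep(dY[-T_, , drop = FALSE], 2, params$kernel[3, ], "*")
  list(dH = dH, grads = list(kernel = dk, bias = dbias))
}

# ---- MLP classifier block: h -> 24 -> 24 -> K, ReLU hidden, softmax out ----

.mlp_forward <- function(v, mlp) {
  z1 <- as.vector(mlp$W1 %*% v + mlp$b1)
  a1 <- pmax(z1, 0)
  z2 <- as.vector(mlp$W2 %*% a1 + mlp$b2)
  a2 <- pmax(z2, 0)
  logits <- as.vector(mlp$W3 %*% a2 + mlp$b3)
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  list(p = p, a1 = a1, a2 = a2, z1 = z1, z2 = z2, v = v)
}

# dlogits = p - onehot for cross-entropy + softmax
.mlp_backward <- function(cache, mlp, dlogits) {
  dW3 <- outer(dlogits, cache$a2)
  db3 <- dlogits
  da2 <- as.vector(t(mlp$W3) %*% dlogits)
  dz2 <- da2 * (cache$z2 > 0)
  dW2 <- outer(dz2, cache$a1)
  db2 <- dz2
  da1 <- as.vector(t(mlp$W2) %*% dz2)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- outer(dz1, cache$v)
  db1 <- dz1
  dv <- as.vector(t(mlp$W1) %*% dz1)
  list(dv = dv, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                             W3 = dW3, b3 = db3))
}
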