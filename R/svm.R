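#' Feature standardiser
#'
#' Per-feature z-scoring parameters estimated from a training matrix.
#' Columns with zero variance pass through unscaled (sd set to 1).
#'
#' @param X Numeric matrix, samples in rows.
#' @return List with `mean` and `sd` vectors, class `standardizer`.
#' @export
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  structure(list(mean = mu, sd = sd), class = "standardizer")
}

#' Apply a standardiser
#' @param std A `standardizer`.
#' @param X Matrix with the same columns as the training matrix.
#' @return Standardised matrix.
#' @export
apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")
}

#' Fit the SVM baseline classifier
#'
#' Radial-basis-function kernel support vector machine on standard-scaled
#' video-level features, with regularisation parameter C = 1 and the kernel
#' gamma set by the "scale" rule, `1 / (d * var(X))`, where `var(X)` is the
#' variance of the (scaled) training matrix as a whole. Serves as the
#' non-deep baseline for both the valence and the 16-class task, and as the
#' scoring model for subject difficulty.
#'
#' @param X Numeric n x d matrix of video-level features.
#' @param y Vector of class labels (at least 2 distinct classes).
#' @return A fitted model of class `svm_baseline` with a [predict()] method
#'   returning hard labels.
#' @export
fit_svm_baseline <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("degenerate training set: only one class present")
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  std <- fit_standardizer(X)
  Xs <- apply_standardizer(std, X)
  gamma <- 1 / (ncol(Xs) * stats::var(as.vector(Xs)))
  fit <- e1071::svm(x = Xs, y = factor(y), kernel = "radial", cost = 1,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, standardizer = std, classes = sort(unique(y)),
                 gamma = gamma),
            class = "svm_baseline")
}

#' @export
predict.svm_baseline <- function(object, newdata, ...) {
  Xs <- apply_standardizer(object$standardizer, as.matrix(newdata))
  as.character(stats::predict(object$fit, Xs))
}
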