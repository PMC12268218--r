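#' Contingency (confusion) matrix
#'
#' Builds the K x K contingency matrix A of a classification outcome, where
#' `A[i, j]` counts the instances of true class i predicted as class j. Rows
#' and columns follow the order of `class_names`.
#'
#' @param truth Character vector of true labels.
#' @param pred Character vector of predicted labels, same length.
#' @param class_names Character vector fixing the class set and order.
#'   Defaults to the sorted union of the labels observed.
#' @return Integer K x K matrix of class `contingency_matrix`, with
#'   dimnames `truth` x `predicted`.
#' @export
#' @examples
#' contingency(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
contingency <- function(truth, pred, class_names = NULL) {
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  if (length(truth) < 1) stop("cannot build a contingency matrix from no items")
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (is.null(class_names)) class_names <- sort(unique(c(truth, pred)))
  unknown <- setdiff(unique(c(truth, pred)), class_names)
  if (length(unknown) > 0) {
    stop("label(s) not in class_names: ", paste(unknown, collapse = ", "))
  }
  tab <- table(factor(truth, levels = class_names),
               factor(pred, levels = class_names))
  A <- matrix(as.integer(tab), nrow = length(class_names),
              dimnames = list(truth = class_names, predicted = class_names))
  class(A) <- c("contingency_matrix", class(A))
  A
}

#' Unweighted average recall (UAR)
#'
#' The mean over classes of the per-class recall `A[i, i] / sum(A[i, ])`.
#' Classes with no true instances (empty rows) are excluded from the
#' average, so the UAR of a K-class problem in which all classes are present
#' has chance level 1/K regardless of class imbalance.
#'
#' @param A A contingency matrix (rows = truth, columns = predictions).
#' @return UAR as a fraction in `[0, 1]`.
#' @export
uar <- function(A) {
  rs <- rowSums(A)
  present <- rs > 0
  if (!any(present)) stop("contingency matrix has no observed classes")
  mean(diag(A)[present] / rs[present])
}

#' Classification accuracy
#'
#' Fraction of correctly classified instances: `sum(diag(A)) / sum(A)`.
#'
#' @param A A contingency matrix.
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
accuracy <- function(A) {
  total <- sum(A)
  if (total == 0) stop("empty contingency matrix")
  sum(diag(A)) / total
}

#' Per-class balanced accuracy
#'
#' For each class c, the one-vs-rest balanced accuracy
#' `(sensitivity_c + specificity_c) / 2`, where sensitivity is the recall of
#' class c and specificity the fraction of non-c instances not predicted as
#' c. Classes with neither true nor predicted instances are undefined and
#' returned as `NA`.
#'
#' @param A A contingency matrix.
#' @return Named numeric vector, one balanced accuracy per class.
#' @export
per_class_balanced_accuracy <- function(A) {
  total <- sum(A)
  classes <- rownames(A)
  out <- vapply(seq_along(classes), function(i) {
    tp <- A[i, i]
    pos <- sum(A[i, ])          # true instances of class i
    pred_i <- sum(A[, i])       # predicted as class i
    neg <- total - pos
    if (pos == 0 && pred_i == 0) return(NA_real_)
    sens <- if (pos > 0) tp / pos else NA_real_
    spec <- if (neg > 0) (neg - (pred_i - tp)) / neg else NA_real_
    mean(c(sens, spec), na.rm = TRUE)
  }, numeric(1))
  names(out) <- classes
  out
}

#' Per-class recall
#'
#' The plain recall (sensitivity) of each class, `A[i, i] / sum(A[i, ])`;
#' `NA` for classes with no true instances. Reported alongside
#' [per_class_balanced_accuracy()] so both readings of per-class accuracy
#' are available explicitly.
#'
#' @param A A contingency matrix.
#' @return Named numeric vector.
#' @export
per_class_recall <- function(A) {
  rs <- rowSums(A)
  out <- ifelse(rs > 0, diag(A) / rs, NA_real_)
  names(out) <- rownames(A)
  out
}
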