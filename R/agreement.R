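#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with observed
#' agreement `p_o` the fraction of items labelled identically and expected
#' agreement `p_e` the sum over categories of the product of the two raters'
#' marginal proportions. If both raters assign a single identical category
#' to every item (`p_e == 1`), agreement is perfect and kappa is defined
#' as 1; if `p_e == 1` with disagreement present kappa is undefined and an
#' error is raised.
#'
#' @param r1,r2 Character vectors of labels, same length.
#' @return Cohen's kappa (at most 1).
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("rater vectors must have equal length")
  if (length(r1) < 1) stop("no items to compare")
  r1 <- as.character(r1)
  r2 <- as.character(r2)
  cats <- sort(unique(c(r1, r2)))
  n <- length(r1)
  po <- mean(r1 == r2)
  p1 <- table(factor(r1, levels = cats)) / n
  p2 <- table(factor(r2, levels = cats)) / n
  pe <- sum(as.numeric(p1) * as.numeric(p2))
  if (1 - pe < .Machine$double.eps) {
    if (po == 1) return(1)
    stop("expected agreement is 1 but raters disagree; kappa undefined")
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for a fixed number of raters each labelling
#' every item. Uses the standard formulation: with `n_ij` the number of
#' raters assigning category j to item i and m raters,
#' `P_i = (sum_j n_ij^2 - m) / (m (m - 1))`, `P_bar` their mean,
#' `P_e = sum_j p_j^2` with `p_j` the overall category proportions, and
#' `kappa = (P_bar - P_e) / (1 - P_e)`.
#'
#' @param ratings Matrix (or data.frame) of labels, items in rows, raters in
#'   columns; at least 2 raters.
#' @return Fleiss' kappa (at most 1).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  m <- ncol(ratings)
  if (n < 1) stop("no items")
  if (m < 2) stop("Fleiss' kappa needs at least 2 raters")
  cats <- sort(unique(as.character(ratings)))
  counts <- vapply(cats, function(k) rowSums(ratings == k), numeric(n))
  counts <- matrix(counts, nrow = n)  # n x K
  p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * m)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps) {
    if (p_bar == 1) return(1)
    stop("expected agreement is 1 but raters disagree; kappa undefined")
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Interpret a kappa value
#'
#' Standard interpretation heuristic: slight (kappa <= 0.2), fair
#' (0.2 < kappa <= 0.4), moderate (0.4 < kappa <= 0.6), substantial
#' (0.6 < kappa <= 0.8), almost perfect (kappa > 0.8).
#'
#' @param kappa Numeric kappa value.
#' @return Character label.
#' @export
kappa_label <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1)
  if (kappa <= 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "almost perfect"
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples item indices with replacement B times, recomputes `metric` on
#' each resample's (truth, prediction) pairs, and returns the percentile
#' interval of the resampled values.
#'
#' @param truth,pred Label vectors of equal length.
#' @param metric Function taking a contingency matrix and returning a
#'   scalar, e.g. [accuracy()] or [uar()].
#' @param class_names Class set passed to [contingency()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(truth, pred, metric = accuracy, class_names = NULL,
                         B = 1000, level = 0.95, seed = 1L) {
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  n <- length(truth)
  if (is.null(class_names)) class_names <- sort(unique(c(truth, pred)))
  stats <- withr_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric(contingency(truth[idx], pred[idx], class_names))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' One-sided exact binomial test against chance
#'
#' Exact upper-tail binomial test of whether the observed number of correct
#' classifications exceeds what chance level `p0` would produce.
#'
#' @param n_correct Number of correct classifications.
#' @param n Number of items.
#' @param p0 Chance probability of a correct classification.
#' @return The one-sided p-value `P(X >= n_correct)` for
#'   `X ~ Binomial(n, p0)`.
#' @export
binomial_test_above_chance <- function(n_correct, n, p0) {
  stopifnot(n_correct >= 0, n_correct <= n, p0 > 0, p0 < 1)
  stats::binom.test(n_correct, n, p = p0, alternative = "greater")$p.value
}

#' Evaluate predictions against ground truth
#'
#' Computes the full evaluation report for one rater or model against the
#' ground truth: accuracy with a percentile-bootstrap confidence interval,
#' UAR, per-class recall and balanced accuracy, Cohen's kappa against the
#' truth with its interpretation label, and the one-sided binomial p-value
#' against chance level `1 / K`.
#'
#' @param truth,pred Label vectors of equal length.
#' @param class_names Class set and order (default: the 16 emotions when all
#'   labels are emotions, otherwise the sorted label union).
#' @param B Bootstrap replicates for the CI.
#' @param seed Seed for the bootstrap.
#' @return A list of class `evaluation_report`.
#' @export
evaluation_report <- function(truth, pred, class_names = NULL, B = 1000, seed = 1L) {
  if (is.null(class_names)) {
    all_lab <- unique(c(truth, pred))
    class_names <- if (all(all_lab %in% emotion_labels())) emotion_labels()
                   else if (all(all_lab %in% valence_levels())) valence_levels()
                   else sort(all_lab)
  }
  A <- contingency(truth, pred, class_names)
  acc <- accuracy(A)
  n <- length(truth)
  ci <- bootstrap_ci(truth, pred, metric = accuracy, class_names = class_names,
                     B = B, seed = seed)
  kap <- cohen_kappa(as.character(truth), as.character(pred))
  p0 <- 1 / length(class_names)
  structure(
    list(
      n = n,
      confusion = A,
      accuracy = acc,
      uar = uar(A),
      per_class_recall = per_class_recall(A),
      per_class_balanced_accuracy = per_class_balanced_accuracy(A),
      cohen_kappa = kap,
      kappa_label = kappa_label(kap),
      ci_low = unname(ci["low"]),
      ci_high = unname(ci["high"]),
      p_above_chance = binomial_test_above_chance(round(acc * n), n, p0),
      chance_level = p0
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d items, %d classes\n",
              x$n, nrow(x$confusion)))
  cat(sprintf("  accuracy %.1f%% (95%% CI %.1f-%.1f), UAR %.1f%%\n",
              100 * x$accuracy, 100 * x$ci_low, 100 * x$ci_high, 100 * x$uar))
  cat(sprintf("  Cohen kappa %.3f (%s), p(above chance) %.3g\n",
              x$cohen_kappa, x$kappa_label, x$p_above_chance))
  invisible(x)
}
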