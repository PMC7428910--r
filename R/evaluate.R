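#' Confusion matrix of true against predicted quadrant labels
#'
#' @param true_labels,predicted_labels equal-length label vectors (factor or
#'   character).
#' @param levels the label levels defining row/column order; default
#'   quadrants I-IV.
#' @return a \code{levels} x \code{levels} integer matrix, rows = true,
#'   columns = predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             levels = c("I", "II", "III", "IV")) {
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted labels must have equal length", call. = FALSE)
  tt <- table(true = factor(as.character(true_labels), levels = levels),
              predicted = factor(as.character(predicted_labels),
                                 levels = levels))
  cm <- unclass(as.matrix(tt))
  storage.mode(cm) <- "integer"
  cm
}

#' Classification accuracy from a confusion matrix
#'
#' The proportion of correctly classified cases: the matrix trace over its
#' total, i.e. one minus the misclassification share.
#'
#' @param cm a square count matrix (rows true, columns predicted).
#' @return accuracy in [0, 1].
#' @examples
#' accuracy(diag(c(5, 59, 246, 14)) + 0)  # 1 on a diagonal matrix
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' Linear discriminant baseline classifier
#'
#' Equal-prior linear discriminant analysis: class mean vectors, pooled
#' within-class covariance, and the linear score
#' \eqn{x' S^{-1} \mu_k - \mu_k' S^{-1} \mu_k / 2} maximized over classes.
#' A singular pooled covariance is ridge-regularized (1e-6 on the diagonal)
#' automatically, with a warning.
#'
#' @param features persons x k numeric feature matrix.
#' @param labels per-person class labels.
#' @param ridge diagonal regularization applied when the pooled covariance
#'   cannot be inverted.
#' @return factor of predicted labels (levels = observed label levels).
#' @export
discriminant_baseline <- function(features, labels, ridge = 1e-6) {
  features <- as.matrix(features)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nrow(features) != length(labels))
    stop("features and labels must have equal length", call. = FALSE)
  lev <- levels(labels)
  if (length(lev) < 2) stop("need at least 2 classes", call. = FALSE)
  k <- ncol(features)
  mu <- t(vapply(lev, function(g)
    colMeans(features[labels == g, , drop = FALSE]), numeric(k)))
  S <- matrix(0, k, k)
  for (g in lev) {
    xg <- features[labels == g, , drop = FALSE]
    if (nrow(xg) > 1)
      S <- S + crossprod(scale(xg, center = TRUE, scale = FALSE))
  }
  S <- S / (nrow(features) - length(lev))
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv)) || rcond(S) < 1e-12) {
    warning("singular pooled covariance; applying ridge regularization (",
            ridge, ")", call. = FALSE)
    Sinv <- solve(S + diag(ridge, k))
  }
  B <- Sinv %*% t(mu)                         # k x classes
  const <- -0.5 * colSums(t(mu) * B)          # per class
  scores <- sweep(features %*% B, 2, const, `+`)
  factor(lev[max.col(scores, ties.method = "first")], levels = lev)
}

#' Required survey sample size with finite-population correction
#'
#' Worst-case proportion sample size
#' \eqn{n_0 = z^2 p(1-p) / \mathrm{margin}^2} corrected for a finite
#' population, \eqn{n = n_0 / (1 + (n_0 - 1)/N)}, rounded up. With the
#' defaults (95\% confidence, 5-point margin, p = 0.5) a population of 1521
#' requires 307 respondents.
#'
#' @param population population size (may be \code{Inf}).
#' @param confidence confidence level in (0, 1).
#' @param margin half-width of the confidence interval, in (0, 1).
#' @param p anticipated proportion; 0.5 is the worst case.
#' @return integer sample size.
#' @examples
#' required_sample_size(1521)  # 307
#' required_sample_size(Inf)   # 385
#' @export
required_sample_size <- function(population, confidence = 0.95,
                                 margin = 0.05, p = 0.5) {
  if (!is.numeric(population) || population < 1)
    stop("population must be at least 1", call. = FALSE)
  if (!is.numeric(margin) || margin <= 0 || margin >= 1)
    stop("margin must lie strictly between 0 and 1", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie strictly between 0 and 1", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * p * (1 - p) / margin^2
  n <- if (is.infinite(population)) n0 else n0 / (1 + (n0 - 1) / population)
  as.integer(ceiling(n))
}

#' Survey return rate as a percentage
#'
#' @param returned number of eligible questionnaires returned.
#' @param delivered number delivered.
#' @return percentage (0-100).
#' @examples
#' response_rate(352, 642)  # 54.8...
#' @export
response_rate <- function(returned, delivered) {
  if (delivered <= 0) stop("delivered must be positive", call. = FALSE)
  100 * returned / delivered
}
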