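#' Expected scores and model variances under the continuous Rasch model
#'
#' For a person at ability \code{theta} and items at difficulties
#' \code{difficulties}, the continuous-response Rasch model predicts
#' \deqn{E_j = m + (M - m)\,\sigma(\theta - \delta_j)} with \eqn{\sigma} the
#' logistic function and \eqn{[m, M]} the response range. The model variance is
#' \deqn{W_j = (M - m)^2 \, p_j (1 - p_j) / \nu,\qquad p_j = \sigma(\theta - \delta_j),}
#' where \eqn{\nu} (\code{dispersion}) is a precision constant. With
#' \code{dispersion = 1} the variance is the scaled-Bernoulli form; with
#' \code{dispersion = M - m} it is the binomial-trials form
#' \eqn{(M-m)p(1-p)} appropriate for a Likert scale read as \eqn{M-m} unit
#' steps (the convention \code{\link{fit_rasch}} uses by default).
#'
#' @param theta person ability (logits); scalar or vector.
#' @param difficulties item difficulties (logits).
#' @param response_min,response_max response range endpoints \eqn{m < M}.
#' @param dispersion positive precision constant \eqn{\nu} dividing the
#'   scaled-Bernoulli variance. Default 1.
#' @return list with components \code{expected} and \code{variance}; vectors of
#'   \code{length(difficulties)} when \code{theta} is scalar, otherwise
#'   \code{length(theta) x length(difficulties)} matrices.
#' @examples
#' ev <- expected_and_variance(0, 0, 1, 5)
#' ev$expected  # 3: the midpoint
#' ev$variance  # 4: 16 * 0.25
#' @export
expected_and_variance <- function(theta, difficulties, response_min,
                                  response_max, dispersion = 1) {
  if (!is.numeric(response_min) || !is.numeric(response_max) ||
      response_max <= response_min)
    stop("response_max must exceed response_min", call. = FALSE)
  if (!all(is.finite(theta)) || !all(is.finite(difficulties)))
    stop("theta and difficulties must be finite", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  span <- response_max - response_min
  eta <- outer(theta, difficulties, `-`)
  p <- stats::plogis(eta)
  expected <- response_min + span * p
  variance <- span^2 * p * (1 - p) / dispersion
  if (length(theta) == 1L) {
    expected <- drop(expected)
    variance <- drop(variance)
  }
  list(expected = expected, variance = variance)
}

#' Outfit mean-square person-fit statistic
#'
#' The outlier-sensitive mean square: the average squared standardized residual
#' \deqn{\mathrm{outfit} = \frac{1}{L} \sum_{j=1}^{L} \frac{(O_j - E_j)^2}{W_j},}
#' where \eqn{O_j} is the observed response, \eqn{E_j} the model-expected
#' response and \eqn{W_j} the model variance on item \eqn{j}, over the
#' \eqn{L} items. Its expectation is about 1 under model fit; values of 2.0 or
#' more flag aberrant response patterns (careless or random responding).
#'
#' @param observed_row,expected_row,variance_row equal-length numeric vectors
#'   of observed scores, expected scores and model variances.
#' @return a single non-negative number.
#' @examples
#' outfit_mnsq(c(5, 1), c(3, 3), c(4, 4))  # 1.0
#' @export
outfit_mnsq <- function(observed_row, expected_row, variance_row) {
  L <- length(observed_row)
  if (L < 1L || length(expected_row) != L || length(variance_row) != L)
    stop("observed, expected and variance rows must have equal length >= 1",
         call. = FALSE)
  if (any(variance_row <= 0))
    stop("all model variances must be positive", call. = FALSE)
  mean((observed_row - expected_row)^2 / variance_row)
}

## one damped Newton step for each element of a vector of 1-D ability (or,
## with sign flipped, difficulty) problems; resid and info are row sums of
## (O - E) and W/span precomputed by the caller
newton_step <- function(current, score, info, max_step = 1) {
  step <- score / pmax(info, 1e-10)
  step <- pmin(pmax(step, -max_step), max_step)
  current + step
}

#' Fit a continuous-response Rasch model by joint maximum likelihood
#'
#' Persons and items are placed on a common logit scale by alternating Newton
#' updates of person measures \eqn{\theta_i} and item difficulties
#' \eqn{\delta_j} under the expected-score model
#' \eqn{E_{ij} = m + (M-m)\sigma(\theta_i - \delta_j)}. Difficulties are
#' centred to mean zero (the scale anchor). Per-person outfit mean squares are
#' computed from the fitted expectations and variances.
#'
#' Rows with an extreme total (all responses at \code{response_min} or all at
#' \code{response_max}) have no finite maximum-likelihood measure; they receive
#' a 0.3-score-unit adjustment toward the interior (spread over the items)
#' before estimation so every person gets a finite measure. The same
#' adjustment is applied to extreme item columns.
#'
#' @param observed numeric matrix, persons x items, values in
#'   \code{[response_min, response_max]}.
#' @param response_min,response_max the response range.
#' @param dispersion variance precision constant (see
#'   \code{\link{expected_and_variance}}); default \code{NULL} means
#'   \code{response_max - response_min}, the binomial-trials convention under
#'   which a conforming Likert responder has outfit near 1.
#' @param tol convergence tolerance on the largest absolute parameter change.
#' @param max_iter maximum number of alternating iterations.
#' @param extreme_adjust score-unit adjustment for extreme rows/columns.
#' @return an object of class \code{"rasch_fit"}: a list with
#'   \code{measures}, \code{difficulties}, \code{expected}, \code{variances},
#'   \code{outfit}, \code{converged}, \code{iterations}, and the model
#'   constants \code{response_min}, \code{response_max}, \code{dispersion}.
#' @seealso \code{\link{outfit_mnsq}}, \code{\link{classify_cohort}}
#' @examples
#' set.seed(1)
#' obs <- matrix(pmin(pmax(round(3 + rnorm(200)), 1), 5), 20, 10)
#' fit <- fit_rasch(obs, 1, 5)
#' fit
#' @export
fit_rasch <- function(observed, response_min, response_max, dispersion = NULL,
                      tol = 1e-6, max_iter = 500, extreme_adjust = 0.3) {
  observed <- as.matrix(observed)
  if (!is.numeric(observed)) stop("observed must be numeric", call. = FALSE)
  n <- nrow(observed); L <- ncol(observed)
  if (n < 2L || L < 2L)
    stop("need at least 2 persons and 2 items", call. = FALSE)
  m <- response_min; M <- response_max
  if (M <= m) stop("response_max must exceed response_min", call. = FALSE)
  if (any(observed < m - 1e-9) || any(observed > M + 1e-9))
    stop("responses outside [response_min, response_max]", call. = FALSE)
  if (stats::sd(observed) == 0)
    stop("degenerate data: all responses identical", call. = FALSE)
  if (is.null(dispersion)) dispersion <- M - m
  span <- M - m

  ## adjust extreme rows/columns so every parameter has a finite estimate
  work <- observed
  row_min <- rowSums(work) <= L * m + 1e-9
  row_max <- rowSums(work) >= L * M - 1e-9
  if (any(row_min)) work[row_min, ] <- work[row_min, ] + extreme_adjust / L
  if (any(row_max)) work[row_max, ] <- work[row_max, ] - extreme_adjust / L
  col_min <- colSums(work) <= n * m + 1e-9
  col_max <- colSums(work) >= n * M - 1e-9
  if (any(col_min)) work[, col_min] <- work[, col_min] + extreme_adjust / n
  if (any(col_max)) work[, col_max] <- work[, col_max] - extreme_adjust / n

  qlog <- function(x) stats::qlogis(pmin(pmax(x, 1e-4), 1 - 1e-4))
  theta <- qlog((rowMeans(work) - m) / span)
  delta <- -qlog((colMeans(work) - m) / span)
  delta <- delta - mean(delta)

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p <- stats::plogis(outer(theta, delta, `-`))
    E <- m + span * p
    info <- span * p * (1 - p)           # d E / d theta summed below
    theta_new <- newton_step(theta, rowSums(work - E), rowSums(info))
    p <- stats::plogis(outer(theta_new, delta, `-`))
    E <- m + span * p
    info <- span * p * (1 - p)
    delta_new <- newton_step(delta, -colSums(work - E), colSums(info))
    shift <- mean(delta_new)
    delta_new <- delta_new - shift
    theta_new <- theta_new - shift
    change <- max(abs(theta_new - theta), abs(delta_new - delta))
    theta <- theta_new; delta <- delta_new
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("joint maximum likelihood did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)

  ev <- expected_and_variance(theta, delta, m, M, dispersion = dispersion)
  Emat <- ev$expected; Wmat <- ev$variance
  outfit <- rowMeans((observed - Emat)^2 / Wmat)

  structure(list(
    measures = unname(theta), difficulties = unname(delta),
    expected = Emat, variances = Wmat, outfit = unname(outfit),
    converged = converged, iterations = it,
    response_min = m, response_max = M, dispersion = dispersion,
    person_ids = rownames(observed), observed = observed,
    call = match.call()
  ), class = "rasch_fit")
}

#' Measure a single response vector against anchored item difficulties
#'
#' Estimates one person's measure (and outfit) holding the item difficulties
#' fixed, as needed when scoring a new respondent against a calibrated scale.
#'
#' @param responses numeric vector of item responses.
#' @param difficulties anchored item difficulties (logits).
#' @param response_min,response_max response range.
#' @param dispersion variance precision constant; default
#'   \code{response_max - response_min}.
#' @param extreme_adjust score-unit adjustment for extreme vectors.
#' @return list with \code{measure} and \code{outfit}.
#' @export
rasch_measure <- function(responses, difficulties, response_min, response_max,
                          dispersion = response_max - response_min,
                          extreme_adjust = 0.3) {
  L <- length(difficulties)
  if (length(responses) != L)
    stop("responses and difficulties must have equal length", call. = FALSE)
  m <- response_min; M <- response_max; span <- M - m
  work <- responses
  if (sum(work) <= L * m + 1e-9) work <- work + extreme_adjust / L
  if (sum(work) >= L * M - 1e-9) work <- work - extreme_adjust / L
  theta <- stats::qlogis(pmin(pmax((mean(work) - m) / span, 1e-4), 1 - 1e-4))
  for (i in 1:200) {
    p <- stats::plogis(theta - difficulties)
    E <- m + span * p
    step <- sum(work - E) / max(sum(span * p * (1 - p)), 1e-10)
    step <- max(min(step, 1), -1)
    theta <- theta + step
    if (abs(step) < 1e-8) break
  }
  ev <- expected_and_variance(theta, difficulties, m, M, dispersion)
  list(measure = theta,
       outfit = outfit_mnsq(responses, ev$expected, ev$variance))
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("Continuous-response Rasch fit (joint maximum likelihood)\n")
  cat(sprintf("  %d persons, %d items, responses in [%g, %g], dispersion %g\n",
              length(x$measures), length(x$difficulties),
              x$response_min, x$response_max, x$dispersion))
  cat(sprintf("  converged: %s after %d iterations\n",
              ifelse(x$converged, "yes", "NO"), x$iterations))
  cat(sprintf("  measures:  mean %.3f, sd %.3f logits\n",
              mean(x$measures), stats::sd(x$measures)))
  cat(sprintf("  outfit MNSQ: mean %.3f, %d person(s) >= 2.0\n",
              mean(x$outfit), sum(x$outfit >= 2)))
  invisible(x)
}

#' @export
summary.rasch_fit <- function(object, ...) {
  out <- list(
    n_persons = length(object$measures),
    n_items = length(object$difficulties),
    converged = object$converged,
    measures = summary(object$measures),
    difficulties = object$difficulties,
    outfit = summary(object$outfit),
    n_misfit = sum(object$outfit >= 2)
  )
  class(out) <- "summary.rasch_fit"
  out
}

#' @export
print.summary.rasch_fit <- function(x, ...) {
  cat("Rasch fit:", x$n_persons, "persons x", x$n_items, "items\n")
  cat("Person measures (logits):\n"); print(x$measures)
  cat("Item difficulties (logits):\n")
  print(round(x$difficulties, 3))
  cat("Person outfit MNSQ:\n"); print(x$outfit)
  cat(x$n_misfit, "person(s) with outfit >= 2.0\n")
  invisible(x)
}

#' @export
coef.rasch_fit <- function(object, ...) {
  list(measures = object$measures, difficulties = object$difficulties)
}

#' @export
fitted.rasch_fit <- function(object, ...) object$expected

#' @export
residuals.rasch_fit <- function(object,
                                type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  r <- object$observed - object$expected
  if (type == "standardized") r <- r / sqrt(object$variances)
  r
}

#' Person map: measure against outfit with the four-quadrant cutoffs
#'
#' @param x a \code{rasch_fit}.
#' @param measure_cut,outfit_cut the quadrant cutoffs drawn as reference lines.
#' @param ... passed to \code{plot}.
#' @export
plot.rasch_fit <- function(x, measure_cut = 0, outfit_cut = 2, ...) {
  q <- classify_person(x$measures, x$outfit, measure_cut, outfit_cut)
  graphics::plot(x$outfit, x$measures, col = as.integer(q), pch = 19,
                 xlab = "Outfit MNSQ", ylab = "Measure (logits)", ...)
  graphics::abline(h = measure_cut, v = outfit_cut, lty = 2)
  invisible(x)
}

#' Category-probability curves of the Rasch rating scale model
#'
#' For an item of difficulty \eqn{\delta} with step thresholds
#' \eqn{\tau_1, \dots, \tau_{K-1}}, the probability of category
#' \eqn{k \in \{0, \dots, K-1\}} at ability \eqn{\theta} is
#' \deqn{P(k \mid \theta) = \frac{\exp \sum_{h \le k} (\theta - \delta - \tau_h)}
#'   {\sum_{c} \exp \sum_{h \le c} (\theta - \delta - \tau_h)},}
#' with the empty sum equal to 0 for the lowest category. Each row of the
#' returned probability matrix sums to exactly 1; adjacent categories
#' \eqn{k-1} and \eqn{k} are equiprobable at \eqn{\theta = \delta + \tau_k}.
#'
#' @param difficulty item difficulty (logits).
#' @param thresholds numeric vector of step thresholds (logits); \eqn{K-1}
#'   thresholds give \eqn{K} categories.
#' @param grid ability values at which to evaluate the curves.
#' @return object of class \code{"rating_scale_curves"}: list with
#'   \code{grid}, \code{probabilities} (grid x K matrix), \code{thresholds},
#'   \code{difficulty}.
#' @examples
#' cur <- rating_scale_curves(0, c(-1, 0, 1), seq(-4, 4, 0.5))
#' rowSums(cur$probabilities)  # all 1
#' @export
rating_scale_curves <- function(difficulty, thresholds,
                                grid = seq(-4, 4, by = 0.1)) {
  if (!all(is.finite(thresholds)) || !is.finite(difficulty))
    stop("difficulty and thresholds must be finite", call. = FALSE)
  if (length(grid) < 1L) stop("grid must be non-empty", call. = FALSE)
  K <- length(thresholds) + 1L
  ## cumulative numerator exponents: psi_k = sum_{h<=k} (theta - delta - tau_h)
  cumtau <- c(0, cumsum(thresholds))
  expo <- outer(grid - difficulty, 0:(K - 1L)) -
    matrix(cumtau, length(grid), K, byrow = TRUE)
  expo <- expo - apply(expo, 1L, max)   # stabilize
  num <- exp(expo)
  probs <- num / rowSums(num)
  colnames(probs) <- paste0("cat", 0:(K - 1L))
  structure(list(grid = grid, probabilities = probs,
                 thresholds = thresholds, difficulty = difficulty),
            class = "rating_scale_curves")
}

#' @export
print.rating_scale_curves <- function(x, ...) {
  cat("Rating-scale category probability curves:",
      ncol(x$probabilities), "categories,",
      length(x$grid), "grid points\n")
  cat("item difficulty", x$difficulty, "logits; thresholds:",
      paste(x$thresholds, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.rating_scale_curves <- function(x, ...) {
  graphics::matplot(x$grid, x$probabilities, type = "l", lty = 1,
                    xlab = "Measure (logits)", ylab = "Category probability",
                    ...)
  invisible(x)
}

#' Write category-probability curves to CSV
#'
#' @param curves a \code{rating_scale_curves} object.
#' @param path output CSV path; columns: \code{measure}, one per category.
#' @return the path, invisibly.
#' @export
write_curves <- function(curves, path) {
  df <- data.frame(measure = curves$grid, curves$probabilities,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
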