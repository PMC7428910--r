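#' The eight questionnaire domains
#'
#' Item-to-domain assignment of the 44-item instrument: eight domains named
#' mental health, attitude to patients, diversified, adjustment, persevering,
#' teamwork, physical health and behavior, with 16, 5, 4, 4, 5, 4, 4 and 2
#' items respectively.
#'
#' @param domain_sizes items per domain.
#' @param domain_names one label per domain.
#' @return an object of class \code{"domain_spec"}: list with
#'   \code{domain_names}, \code{domain_sizes}, and \code{item_assignment}
#'   (item index to domain index).
#' @export
elmh_domains <- function(domain_sizes = c(16, 5, 4, 4, 5, 4, 4, 2),
                         domain_names = c("mental health",
                                          "attitude to patients",
                                          "diversified", "adjustment",
                                          "persevering", "teamwork",
                                          "physical health", "behavior")) {
  if (length(domain_names) != length(domain_sizes))
    stop("domain_names and domain_sizes must have equal length",
         call. = FALSE)
  structure(list(domain_names = domain_names,
                 domain_sizes = as.integer(domain_sizes),
                 item_assignment = rep(seq_along(domain_sizes),
                                       domain_sizes)),
            class = "domain_spec")
}

#' Per-domain raw sum scores
#'
#' @param responses persons x items numeric matrix.
#' @param domains a \code{\link{elmh_domains}} spec.
#' @return persons x domains matrix of raw sums.
#' @export
domain_sums <- function(responses, domains = elmh_domains()) {
  responses <- as.matrix(responses)
  if (ncol(responses) != length(domains$item_assignment))
    stop("responses have ", ncol(responses), " items but the domain spec ",
         "assigns ", length(domains$item_assignment), call. = FALSE)
  sums <- sapply(seq_along(domains$domain_sizes), function(d)
    rowSums(responses[, domains$item_assignment == d, drop = FALSE]))
  if (nrow(responses) == 1L) sums <- matrix(sums, nrow = 1L)
  colnames(sums) <- paste0("sum", seq_along(domains$domain_sizes))
  sums
}

#' Number of factors retained by the eigenvalue rule
#'
#' Retains every factor whose eigenvalue is at least 1.0 (inclusive
#' threshold).
#'
#' @param eigenvalues eigenvalues of the correlation matrix, sorted
#'   descending.
#' @return integer count; 0 (with a warning) when no eigenvalue reaches 1.0.
#' @examples
#' retain_factors(c(3.2, 1.5, 1.0, 0.4))  # 3
#' @export
retain_factors <- function(eigenvalues) {
  if (length(eigenvalues) == 0)
    stop("eigenvalues must be non-empty", call. = FALSE)
  if (is.unsorted(rev(eigenvalues), strictly = FALSE))
    stop("eigenvalues must be sorted in descending order", call. = FALSE)
  k <- sum(eigenvalues >= 1.0)
  if (k == 0)
    warning("no eigenvalue reaches the 1.0 retention criterion",
            call. = FALSE)
  as.integer(k)
}

#' Exploratory factor extraction with varimax rotation
#'
#' Principal-component extraction from the item correlation matrix: the
#' loading matrix is built from the leading eigenvectors scaled by the square
#' roots of their eigenvalues, then varimax-rotated (orthogonal rotation,
#' which leaves each item's communality unchanged). Uniqueness is one minus
#' the communality.
#'
#' @param responses persons x items numeric matrix.
#' @param n_factors number of factors to extract.
#' @param rotate \code{"varimax"} (default) or \code{"none"}.
#' @return object of class \code{"elmh_efa"}: list with \code{loadings}
#'   (items x factors), \code{uniquenesses}, \code{eigenvalues},
#'   \code{center} and \code{scale} (item means and SDs used for
#'   standardization), \code{rotation}.
#' @export
extract_factors <- function(responses, n_factors,
                            rotate = c("varimax", "none")) {
  rotate <- match.arg(rotate)
  responses <- as.matrix(responses)
  if (n_factors < 1) stop("n_factors must be at least 1", call. = FALSE)
  if (n_factors > ncol(responses))
    stop("n_factors cannot exceed the number of items", call. = FALSE)
  sds <- apply(responses, 2, stats::sd)
  if (any(sds == 0) || anyNA(sds))
    stop("singular correlation matrix: zero-variance item(s) ",
         paste(which(sds == 0 | is.na(sds)), collapse = ", "),
         call. = FALSE)
  R <- stats::cor(responses)
  if (anyNA(R)) stop("correlation matrix has missing entries", call. = FALSE)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  if (ev[n_factors] <= 0)
    stop("estimation error: correlation matrix is singular at ", n_factors,
         " factors", call. = FALSE)
  L <- eig$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_factors)]), n_factors)
  if (rotate == "varimax" && n_factors > 1L)
    L <- stats::varimax(L)$loadings[, , drop = FALSE]
  L <- unclass(L)
  ## orient each factor so its dominant loadings are positive
  flip <- sign(colSums(L^3)); flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, `*`)
  rownames(L) <- colnames(responses)
  colnames(L) <- paste0("F", seq_len(n_factors))
  communality <- rowSums(L^2)
  structure(list(loadings = L,
                 uniquenesses = 1 - communality,
                 eigenvalues = ev,
                 center = colMeans(responses), scale = sds,
                 rotation = rotate),
            class = "elmh_efa")
}

#' @export
print.elmh_efa <- function(x, ...) {
  cat("Exploratory factor extraction:", ncol(x$loadings), "factors,",
      nrow(x$loadings), "items (", x$rotation, "rotation )\n")
  cat("Eigenvalues >= 1.0:", sum(x$eigenvalues >= 1), "\n")
  cat("Variance explained:",
      sprintf("%.1f%%", 100 * sum(x$loadings^2) / nrow(x$loadings)), "\n")
  invisible(x)
}

#' Bartlett weighted least-squares factor scores
#'
#' Given loadings \eqn{\Lambda} and uniquenesses \eqn{\Psi} (diagonal), the
#' Bartlett score of a standardized response vector \eqn{z} is
#' \deqn{F = (\Lambda' \Psi^{-1} \Lambda)^{-1} \Lambda' \Psi^{-1} z.}
#' Standardization uses the cohort's item means and SDs; when scoring new
#' respondents against a stored model, pass the stored \code{center} and
#' \code{scale} so single persons are standardized consistently.
#'
#' @param responses persons x items numeric matrix.
#' @param loadings items x factors loading matrix, or an \code{elmh_efa}
#'   object (in which case \code{uniquenesses}, \code{center} and
#'   \code{scale} are taken from it).
#' @param uniquenesses per-item uniquenesses in (0, 1].
#' @param center,scale item means and SDs for standardization; default: the
#'   cohort's own.
#' @return persons x factors matrix of factor scores.
#' @export
bartlett_scores <- function(responses, loadings, uniquenesses = NULL,
                            center = NULL, scale = NULL) {
  responses <- as.matrix(responses)
  if (inherits(loadings, "elmh_efa")) {
    efa <- loadings
    loadings <- efa$loadings
    if (is.null(uniquenesses)) uniquenesses <- efa$uniquenesses
    if (is.null(center)) center <- efa$center
    if (is.null(scale)) scale <- efa$scale
  }
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != ncol(responses))
    stop("loadings rows must match the number of items", call. = FALSE)
  if (length(uniquenesses) != nrow(loadings))
    stop("uniquenesses must have one entry per item", call. = FALSE)
  if (any(uniquenesses <= 0))
    stop("singularity error: zero or negative uniqueness", call. = FALSE)
  if (is.null(center)) center <- colMeans(responses)
  if (is.null(scale)) scale <- apply(responses, 2, stats::sd)
  if (any(scale == 0))
    stop("zero-variance item(s); cannot standardize", call. = FALSE)
  z <- sweep(sweep(responses, 2, center, `-`), 2, scale, `/`)
  Pi <- loadings / uniquenesses                   # Psi^{-1} Lambda
  A <- solve(crossprod(loadings, Pi))             # (L' Psi^-1 L)^-1
  scores <- z %*% Pi %*% t(A)
  colnames(scores) <- colnames(loadings)
  scores
}

#' The shipped sum-to-factor-score regression mapping
#'
#' The eight per-domain linear mappings from domain raw sum to factor score
#' used by the assessment path, as estimated on the study cohort:
#' \deqn{F_d = a_d + b_d \cdot \mathrm{sum}_d .}
#'
#' @return an object of class \code{"score_regression"}: data frame with
#'   columns \code{domain}, \code{intercept}, \code{slope}.
#' @examples
#' regression_factor_score(1, 0)   # the domain-1 intercept, -3.2516
#' @export
default_score_regression <- function() {
  structure(data.frame(
    domain = 1:8,
    intercept = c(-3.2516, -7.7062, -3.6067, -4.7129,
                  -4.9833, -5.4556, -2.5251, -4.2156),
    slope = c(0.08190, 0.3711, 0.3104, 0.3349,
              0.2821, 0.5632, 0.2220, 0.6377)),
    class = c("score_regression", "data.frame"))
}

#' Factor score from a domain raw sum via the regression shortcut
#'
#' @param domain_index integer in 1..8.
#' @param raw_sum domain raw sum (vectorized).
#' @param regression a \code{score_regression}; default the shipped mapping
#'   (\code{\link{default_score_regression}}).
#' @return numeric factor score(s).
#' @export
regression_factor_score <- function(domain_index, raw_sum,
                                    regression = default_score_regression()) {
  if (length(domain_index) != 1 || !domain_index %in% regression$domain)
    stop("domain_index must be a single value in 1..",
         max(regression$domain), call. = FALSE)
  i <- match(domain_index, regression$domain)
  regression$intercept[i] + regression$slope[i] * raw_sum
}

#' Fit per-domain sum-to-factor-score regressions
#'
#' Ordinary least squares of each domain's factor score on its raw sum,
#' reproducing the regression shortcut used for single-respondent scoring.
#'
#' @param raw_sums persons x domains matrix of domain raw sums.
#' @param scores persons x domains matrix of factor scores (domain-aligned).
#' @return a \code{score_regression} data frame.
#' @export
fit_score_regressions <- function(raw_sums, scores) {
  raw_sums <- as.matrix(raw_sums); scores <- as.matrix(scores)
  if (!all(dim(raw_sums) == dim(scores)))
    stop("raw_sums and scores must have identical dimensions", call. = FALSE)
  if (nrow(raw_sums) < 3)
    stop("need at least 3 persons", call. = FALSE)
  coefs <- t(vapply(seq_len(ncol(raw_sums)), function(d) {
    x <- raw_sums[, d]
    if (stats::sd(x) == 0)
      stop("estimation error: zero variance in domain ", d, " raw sums",
           call. = FALSE)
    stats::coef(stats::lm(scores[, d] ~ x))
  }, numeric(2)))
  structure(data.frame(domain = seq_len(ncol(raw_sums)),
                       intercept = coefs[, 1], slope = coefs[, 2]),
            class = c("score_regression", "data.frame"))
}

## Align extracted factors to questionnaire domains: assign each domain the
## factor carrying the largest share of squared loading mass on its items
## (greedy, largest domains first), and orient the factor so higher domain
## responses raise the score.
align_factors_to_domains <- function(efa, domains) {
  L <- efa$loadings
  k <- ncol(L)
  nd <- length(domains$domain_sizes)
  if (k < nd) stop("fewer factors than domains", call. = FALSE)
  mass <- sapply(seq_len(nd), function(d)
    colSums(L[domains$item_assignment == d, , drop = FALSE]^2))
  ## mass: factors x domains
  assign <- integer(nd)
  taken <- logical(k)
  for (d in order(domains$domain_sizes, decreasing = TRUE)) {
    cand <- order(mass[, d], decreasing = TRUE)
    cand <- cand[!taken[cand]]
    assign[d] <- cand[1]
    taken[cand[1]] <- TRUE
  }
  sgn <- vapply(seq_len(nd), function(d) {
    s <- sum(L[domains$item_assignment == d, assign[d]])
    if (s < 0) -1 else 1
  }, numeric(1))
  list(factor_of_domain = assign, sign = sgn)
}
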