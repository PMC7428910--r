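#' Four-quadrant classification of (measure, outfit) pairs
#'
#' Respondents are divided into four classes by crossing the person measure
#' (cut at 0 logits) with the outfit mean square (cut at 2.0):
#' \itemize{
#'   \item \strong{II} — mental illness (measure above the cut, good fit):
#'     high-confidence positive;
#'   \item \strong{III} — health / MI-free (measure at or below the cut, good
#'     fit): high-confidence negative;
#'   \item \strong{I} — false MI (measure above the cut, misfitting pattern):
#'     low confidence;
#'   \item \strong{IV} — false health (measure at or below the cut,
#'     misfitting): low confidence.
#' }
#' Boundary convention: a measure exactly at the cut falls on the low side
#' (III/IV); an outfit exactly at the cut counts as misfit (I/IV).
#'
#' @param measure person measure(s) in logits.
#' @param outfit non-negative outfit mean square(s).
#' @param measure_cut measure cutoff (default 0 logits).
#' @param outfit_cut outfit cutoff (default 2.0).
#' @return factor with levels \code{I, II, III, IV} (same length as the
#'   inputs).
#' @examples
#' classify_person(c(1.2, -0.7, 1.2, -0.7), c(0.8, 0.9, 2.4, 3.1))
#' @export
classify_person <- function(measure, outfit, measure_cut = 0,
                            outfit_cut = 2.0) {
  if (any(!is.finite(measure)) || any(!is.finite(outfit)))
    stop("measure and outfit must be finite", call. = FALSE)
  if (any(outfit < 0)) stop("outfit must be non-negative", call. = FALSE)
  high <- measure > measure_cut
  misfit <- outfit >= outfit_cut
  q <- ifelse(high,
              ifelse(misfit, "I", "II"),
              ifelse(misfit, "IV", "III"))
  factor(q, levels = c("I", "II", "III", "IV"))
}

#' Confidence attached to a quadrant label
#'
#' Quadrants II and III are measured with good person fit and carry high
#' confidence; I and IV reflect misfitting response patterns and carry low
#' confidence.
#'
#' @param quadrant factor or character vector of quadrant labels.
#' @return character vector, \code{"high"} or \code{"low"}.
#' @export
quadrant_confidence <- function(quadrant) {
  ifelse(as.character(quadrant) %in% c("II", "III"), "high", "low")
}

#' Classify every person in a Rasch fit
#'
#' @param fit a \code{\link{fit_rasch}} object.
#' @param measure_cut,outfit_cut cutoffs passed to
#'   \code{\link{classify_person}}.
#' @return an object of class \code{"quadrant_classification"}: a data frame
#'   with columns \code{person_id}, \code{measure}, \code{outfit},
#'   \code{quadrant}, \code{confidence}, carrying the per-quadrant
#'   \code{counts} as an attribute (also returned by
#'   \code{\link{quadrant_counts}}).
#' @examples
#' set.seed(2)
#' obs <- matrix(pmin(pmax(round(3 + rnorm(300)), 1), 5), 30, 10)
#' classify_cohort(fit_rasch(obs, 1, 5))
#' @export
classify_cohort <- function(fit, measure_cut = 0, outfit_cut = 2.0) {
  stopifnot(inherits(fit, "rasch_fit"))
  q <- classify_person(fit$measures, fit$outfit, measure_cut, outfit_cut)
  ids <- fit$person_ids
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(fit$measures))
  df <- data.frame(person_id = ids, measure = fit$measures,
                   outfit = fit$outfit, quadrant = q,
                   confidence = quadrant_confidence(q),
                   stringsAsFactors = FALSE)
  counts <- table(df$quadrant)
  structure(df, counts = counts,
            class = c("quadrant_classification", "data.frame"))
}

#' Per-quadrant counts of a classification
#'
#' @param x a \code{quadrant_classification}.
#' @return named integer table over quadrants I-IV; sums to the cohort size.
#' @export
quadrant_counts <- function(x) {
  stopifnot(inherits(x, "quadrant_classification"))
  attr(x, "counts")
}

#' @export
print.quadrant_classification <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("Four-quadrant classification of", nrow(x), "persons\n")
  print(counts)
  cat(sprintf("Type III (health) share: %.0f%%\n",
              100 * counts[["III"]] / sum(counts)))
  invisible(x)
}

#' Write per-person quadrant labels to CSV
#'
#' @param x a \code{quadrant_classification}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_labels <- function(x, path) {
  stopifnot(inherits(x, "quadrant_classification"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
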