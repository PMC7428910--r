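#' Configuration for a simulated questionnaire cohort
#'
#' Builds and validates the parameter set for \code{\link{simulate_cohort}}.
#' The defaults emulate the study conditions the pipeline is designed for: a
#' cohort of 352 respondents answering 44 five-point Likert items grouped into
#' 8 domains of sizes 16/5/4/4/5/4/4/2, with a small fraction of careless
#' (uniform random) responders and a mostly-healthy trait distribution
#' (trait mean below the 0-logit cut so that roughly one respondent in five
#' sits on the high-severity side).
#'
#' @param n_persons number of respondents.
#' @param n_items number of items; must equal \code{sum(domain_sizes)}.
#' @param domain_sizes items per domain.
#' @param likert_min,likert_max integer response range.
#' @param trait_mean,trait_sd mean and SD (logits) of the shared latent trait.
#' @param domain_sd SD (logits) of the person-by-domain trait component added
#'   to the shared trait; positive values give the cohort an 8-factor
#'   correlation structure.
#' @param difficulty_spread item difficulties are equally spaced in
#'   \code{[-difficulty_spread, difficulty_spread]} (logits).
#' @param noise_sd SD of the Gaussian response noise (response units) for
#'   model-conforming persons. The default 0.8 matches the model variance of
#'   the continuous Rasch model (binomial-trials dispersion) at the cohort's
#'   typical location, so conforming responders have outfit mean square near 1.
#' @param aberrant_fraction proportion of persons responding uniformly at
#'   random over the Likert range.
#' @param seed integer RNG seed; identical configurations give identical
#'   cohorts.
#' @return an object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_persons = 352, n_items = 44,
                              domain_sizes = c(16, 5, 4, 4, 5, 4, 4, 2),
                              likert_min = 1, likert_max = 5,
                              trait_mean = -0.9, trait_sd = 1,
                              domain_sd = 0.5, difficulty_spread = 1,
                              noise_sd = 0.8, aberrant_fraction = 0.07,
                              seed = 1) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid '", field, "': ", msg, call. = FALSE)
  chk(is.numeric(n_persons) && length(n_persons) == 1 && n_persons >= 0 &&
        n_persons == round(n_persons), "n_persons",
      "must be a single non-negative integer")
  chk(is.numeric(n_items) && n_items >= 1 && n_items == round(n_items),
      "n_items", "must be a positive integer")
  chk(is.numeric(domain_sizes) && all(domain_sizes >= 1) &&
        sum(domain_sizes) == n_items, "domain_sizes",
      "must be positive counts summing to n_items")
  chk(likert_min < likert_max, "likert_min", "likert_min must be < likert_max")
  chk(is.numeric(trait_mean) && is.finite(trait_mean), "trait_mean",
      "must be finite")
  chk(is.numeric(trait_sd) && trait_sd >= 0, "trait_sd",
      "must be non-negative")
  chk(is.numeric(domain_sd) && domain_sd >= 0, "domain_sd",
      "must be non-negative")
  chk(is.numeric(difficulty_spread) && difficulty_spread >= 0,
      "difficulty_spread", "must be non-negative")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd",
      "must be non-negative")
  chk(is.numeric(aberrant_fraction) && aberrant_fraction >= 0 &&
        aberrant_fraction <= 1, "aberrant_fraction", "must lie in [0, 1]")
  chk(is.numeric(seed) && is.finite(seed), "seed", "must be a number")
  structure(list(n_persons = as.integer(n_persons),
                 n_items = as.integer(n_items),
                 domain_sizes = as.integer(domain_sizes),
                 likert_min = likert_min, likert_max = likert_max,
                 trait_mean = trait_mean, trait_sd = trait_sd,
                 domain_sd = domain_sd,
                 difficulty_spread = difficulty_spread,
                 noise_sd = noise_sd,
                 aberrant_fraction = aberrant_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a questionnaire cohort with known latent structure
#'
#' Model-conforming persons respond with their continuous-Rasch expected score
#' plus Gaussian noise, rounded and clipped to the Likert range; aberrant
#' persons respond uniformly at random over the range. Each person carries a
#' shared trait plus an independent per-domain component, so domains form
#' correlated item blocks. After generation, the cohort is run through the
#' package's own Rasch fit and four-quadrant cutoffs (0 logits, outfit 2.0) to
#' record each person's true quadrant label.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return an object of class \code{"elmh_cohort"}: list with
#'   \code{responses} (persons x items integer matrix), \code{true_theta},
#'   \code{true_difficulty}, \code{aberrant_flags}, \code{true_quadrant},
#'   \code{true_measure}, \code{true_outfit} and the \code{config}.
#' @examples
#' coh <- simulate_cohort(simulation_config(n_persons = 60, seed = 7))
#' coh
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  n <- config$n_persons; L <- config$n_items
  m <- config$likert_min; M <- config$likert_max
  n_ab <- round(config$aberrant_fraction * n)
  difficulty <- if (L == 1L) 0 else
    seq(-config$difficulty_spread, config$difficulty_spread, length.out = L)
  difficulty <- difficulty - mean(difficulty)
  dom_of_item <- rep(seq_along(config$domain_sizes), config$domain_sizes)

  out <- with_seed(config$seed, {
    theta <- stats::rnorm(n, config$trait_mean, config$trait_sd)
    u <- matrix(stats::rnorm(n * length(config$domain_sizes), 0,
                             config$domain_sd),
                nrow = n, ncol = length(config$domain_sizes))
    aberrant <- rep(FALSE, n)
    if (n_ab > 0) aberrant[sample.int(n, n_ab)] <- TRUE
    eta <- outer(theta, difficulty, `-`) + u[, dom_of_item, drop = FALSE]
    E <- m + (M - m) * stats::plogis(eta)
    resp <- E + matrix(stats::rnorm(n * L, 0, config$noise_sd), n, L)
    resp <- round(pmin(pmax(resp, m), M))
    if (any(aberrant))
      resp[aberrant, ] <- matrix(
        sample(seq(m, M), sum(aberrant) * L, replace = TRUE),
        ncol = L)
    list(theta = theta, aberrant = aberrant, resp = resp)
  })

  resp <- out$resp
  if (n > 0) {
    rownames(resp) <- sprintf("P%03d", seq_len(n))
    colnames(resp) <- sprintf("i%02d", seq_len(L))
  }

  ## truth labels from the generator-side fit with the pipeline's own cutoffs
  true_quadrant <- factor(character(0), levels = c("I", "II", "III", "IV"))
  true_measure <- numeric(0); true_outfit <- numeric(0)
  if (n >= 2 && L >= 2 && stats::sd(resp) > 0) {
    fit <- fit_rasch(resp, m, M)
    true_measure <- fit$measures
    true_outfit <- fit$outfit
    true_quadrant <- classify_person(fit$measures, fit$outfit)
  }

  structure(list(responses = resp, true_theta = out$theta,
                 true_difficulty = difficulty,
                 aberrant_flags = out$aberrant,
                 true_quadrant = true_quadrant,
                 true_measure = true_measure, true_outfit = true_outfit,
                 config = config),
            class = "elmh_cohort")
}

#' @export
print.elmh_cohort <- function(x, ...) {
  cat("Simulated questionnaire cohort:",
      nrow(x$responses), "persons x", ncol(x$responses), "items\n")
  cat("  Likert range [", x$config$likert_min, ",", x$config$likert_max,
      "], aberrant responders:", sum(x$aberrant_flags), "\n")
  if (length(x$true_quadrant))
    print(table(quadrant = x$true_quadrant))
  invisible(x)
}

#' Write a cohort to CSV with a JSON truth sidecar
#'
#' The response matrix goes to \code{path} as CSV (\code{person_id},
#' \code{i01}...). The generating truth (theta, difficulties, aberrant flags,
#' quadrant labels) goes to a sidecar JSON at \code{path} with extension
#' \code{.truth.json}.
#'
#' @param cohort an \code{elmh_cohort}.
#' @param path output CSV path.
#' @return the CSV path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "elmh_cohort"))
  n <- nrow(cohort$responses)
  df <- data.frame(person_id = if (n) rownames(cohort$responses)
                   else character(0),
                   cohort$responses, check.names = FALSE)
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write cohort CSV to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  truth_path <- sub("\\.csv$", "", path)
  truth_path <- paste0(truth_path, ".truth.json")
  jsonlite::write_json(
    list(schema_version = 1L,
         theta = cohort$true_theta,
         difficulty = cohort$true_difficulty,
         aberrant = cohort$aberrant_flags,
         quadrant = as.character(cohort$true_quadrant)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a response matrix (and truth sidecar, if present) from CSV
#'
#' @param path CSV path as written by \code{\link{write_cohort}} (or any CSV
#'   with a \code{person_id} column followed by item columns).
#' @return list with \code{responses} (numeric matrix with person row names)
#'   and, when the sidecar exists, \code{truth}.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"person_id" %in% names(df))
    stop("cohort CSV must have a 'person_id' column", call. = FALSE)
  resp <- as.matrix(df[setdiff(names(df), "person_id")])
  rownames(resp) <- as.character(df$person_id)
  out <- list(responses = resp)
  truth_path <- paste0(sub("\\.csv$", "", path), ".truth.json")
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    out$truth <- tr
  }
  out
}
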