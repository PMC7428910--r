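#' Fit the full questionnaire classification model to a cohort
#'
#' Runs the complete unsupervised pipeline on a persons x items response
#' matrix:
#' \enumerate{
#'   \item exploratory factor extraction (principal components, varimax) with
#'     \code{n_factors} factors, aligned and sign-oriented to the
#'     questionnaire domains;
#'   \item Bartlett weighted least-squares factor scores, and per-domain
#'     ordinary-least-squares regressions of factor score on domain raw sum
#'     (the single-respondent scoring shortcut);
#'   \item a continuous-response Rasch fit of the raw item responses, giving
#'     each person a measure (logits) and an outfit mean square;
#'   \item the four-quadrant classification at 0 logits and outfit 2.0.
#' }
#'
#' @param responses persons x items numeric matrix (Likert responses).
#' @param domains a \code{\link{elmh_domains}} spec.
#' @param n_factors factors to extract (default: number of domains).
#' @param likert_min,likert_max the response range.
#' @param measure_cut,outfit_cut quadrant cutoffs.
#' @return an object of class \code{"elmh_model"} with components
#'   \code{efa}, \code{factor_scores} (domain-aligned), \code{regressions},
#'   \code{rasch} (the \code{rasch_fit}), \code{classification},
#'   \code{domains}, \code{cuts}; optionally a \code{cnn} added by
#'   \code{\link{add_cnn}}.
#' @seealso \code{\link{assess_respondent}}, \code{\link{save_model}}
#' @export
elmh_model <- function(responses, domains = elmh_domains(),
                       n_factors = length(domains$domain_sizes),
                       likert_min = 1, likert_max = 5,
                       measure_cut = 0, outfit_cut = 2.0) {
  responses <- as.matrix(responses)
  efa <- extract_factors(responses, n_factors)
  scores <- bartlett_scores(responses, efa)
  align <- align_factors_to_domains(efa, domains)
  aligned <- sweep(scores[, align$factor_of_domain, drop = FALSE], 2,
                   align$sign, `*`)
  colnames(aligned) <- paste0("F", seq_along(domains$domain_sizes))
  sums <- domain_sums(responses, domains)
  regressions <- fit_score_regressions(sums, aligned)
  rasch <- fit_rasch(responses, likert_min, likert_max)
  classification <- classify_cohort(rasch, measure_cut, outfit_cut)
  structure(list(efa = efa, factor_scores = aligned,
                 regressions = regressions, rasch = rasch,
                 classification = classification, domains = domains,
                 alignment = align,
                 likert_min = likert_min, likert_max = likert_max,
                 cuts = c(measure = measure_cut, outfit = outfit_cut),
                 call = match.call()),
            class = "elmh_model")
}

#' @export
print.elmh_model <- function(x, ...) {
  cat("Questionnaire mental-health classification model\n")
  cat("  cohort:", nrow(x$factor_scores), "persons,",
      length(x$rasch$difficulties), "items,",
      length(x$domains$domain_sizes), "domains\n")
  print(quadrant_counts(x$classification))
  if (!is.null(x$cnn))
    cat(sprintf("  micro-CNN attached: training accuracy %.2f\n",
                x$cnn$training_accuracy))
  invisible(x)
}

#' @export
summary.elmh_model <- function(object, ...) {
  cat("Domain score regressions (factor score = intercept + slope * sum):\n")
  print(object$regressions, row.names = FALSE)
  cat("\n")
  print(summary(object$rasch))
  invisible(object)
}

#' @export
coef.elmh_model <- function(object, ...) object$regressions

#' @export
plot.elmh_model <- function(x, ...) {
  plot(x$rasch, measure_cut = x$cuts["measure"],
       outfit_cut = x$cuts["outfit"], ...)
}

#' Predict measures, outfit and quadrants for new respondents
#'
#' Scores new response vectors against the fitted model's anchored item
#' difficulties (single-person Rasch measurement) and applies the quadrant
#' cutoffs.
#'
#' @param object an \code{elmh_model}.
#' @param newdata persons x items response matrix or a single response
#'   vector.
#' @param ... unused.
#' @return data frame with \code{measure}, \code{outfit}, \code{quadrant},
#'   \code{confidence}.
#' @export
predict.elmh_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  res <- t(apply(newdata, 1, function(r) {
    mo <- rasch_measure(r, object$rasch$difficulties,
                        object$likert_min, object$likert_max,
                        object$rasch$dispersion)
    c(mo$measure, mo$outfit)
  }))
  q <- classify_person(res[, 1], res[, 2],
                       object$cuts["measure"], object$cuts["outfit"])
  data.frame(measure = res[, 1], outfit = res[, 2], quadrant = q,
             confidence = quadrant_confidence(q))
}

#' Attach a trained micro-CNN to a fitted model
#'
#' Trains the micro network on the cohort's responses against the model's
#' own quadrant labels and stores it in the model bundle.
#'
#' @param model an \code{elmh_model}.
#' @param responses the cohort response matrix the model was fitted to.
#' @param config a \code{\link{cnn_config}}.
#' @return the model with a \code{cnn} component.
#' @export
add_cnn <- function(model, responses, config = cnn_config()) {
  stopifnot(inherits(model, "elmh_model"))
  model$cnn <- train_cnn(responses, model$classification$quadrant, config,
                         likert_min = model$likert_min,
                         likert_max = model$likert_max,
                         n_items = length(model$rasch$difficulties))
  model
}

#' Save / load a fitted model bundle as JSON
#'
#' The bundle stores everything single-respondent assessment needs: factor
#' loadings, uniquenesses, item standardization statistics, the
#' sum-to-score regressions, the anchored Rasch difficulties and model
#' constants, the quadrant cutoffs, and (if attached) the micro-CNN
#' parameters.
#'
#' @param model an \code{elmh_model}.
#' @param path JSON path.
#' @return \code{save_model}: the path, invisibly; \code{load_model}: an
#'   \code{elmh_model} (without cohort-level classification).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "elmh_model"))
  js <- list(
    schema_version = 1L,
    domains = list(names = model$domains$domain_names,
                   sizes = model$domains$domain_sizes),
    likert = c(model$likert_min, model$likert_max),
    cuts = as.list(model$cuts),
    efa = list(loadings = model$efa$loadings,
               uniquenesses = model$efa$uniquenesses,
               center = model$efa$center, scale = model$efa$scale),
    alignment = model$alignment,
    regressions = list(intercept = model$regressions$intercept,
                       slope = model$regressions$slope),
    rasch = list(difficulties = model$rasch$difficulties,
                 dispersion = model$rasch$dispersion,
                 response_min = model$rasch$response_min,
                 response_max = model$rasch$response_max))
  if (!is.null(model$cnn))
    js$cnn <- list(geometry = model$cnn$config[c("n_classes", "input_side",
                                                 "filter_side", "pool_side")],
                   class_levels = model$cnn$class_levels,
                   parameters = as_parameter_vector(model$cnn$parameters))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  domains <- elmh_domains(js$domains$sizes, js$domains$names)
  model <- list(
    efa = structure(list(loadings = as.matrix(js$efa$loadings),
                         uniquenesses = js$efa$uniquenesses,
                         center = js$efa$center, scale = js$efa$scale,
                         rotation = "varimax"),
                    class = "elmh_efa"),
    regressions = structure(
      data.frame(domain = seq_along(js$regressions$intercept),
                 intercept = js$regressions$intercept,
                 slope = js$regressions$slope),
      class = c("score_regression", "data.frame")),
    rasch = list(difficulties = js$rasch$difficulties,
                 dispersion = js$rasch$dispersion,
                 response_min = js$rasch$response_min,
                 response_max = js$rasch$response_max),
    alignment = js$alignment,
    domains = domains,
    likert_min = js$likert[1], likert_max = js$likert[2],
    cuts = c(measure = js$cuts$measure, outfit = js$cuts$outfit))
  if (!is.null(js$cnn)) {
    g <- js$cnn$geometry
    cfg <- cnn_config(n_classes = g$n_classes, input_side = g$input_side,
                      filter_side = g$filter_side, pool_side = g$pool_side)
    if (length(js$cnn$parameters) != count_parameters(cfg))
      stop("model file CNN block holds ", length(js$cnn$parameters),
           " parameters; geometry requires ", count_parameters(cfg),
           call. = FALSE)
    model$cnn <- list(parameters = parameters_from_vector(js$cnn$parameters,
                                                          cfg),
                      config = cfg, class_levels = js$cnn$class_levels,
                      likert_min = js$likert[1], likert_max = js$likert[2],
                      n_items = sum(domains$domain_sizes))
    class(model$cnn) <- "micro_cnn"
  }
  class(model) <- "elmh_model"
  model
}

#' Assess a single respondent
#'
#' Produces the per-respondent report of the assessment path: domain raw
#' sums, regression factor scores, Rasch measure and outfit against the
#' model's anchored difficulties, the quadrant label with its confidence,
#' the micro-CNN class outputs (when a CNN is attached), and an advisory
#' key — \code{"consultation"} for class II, \code{"low confidence"} for
#' I/IV, \code{"no action"} for III.
#'
#' @param responses complete response vector (one value per item).
#' @param model a fitted or loaded \code{\link{elmh_model}}.
#' @param person_id identifier recorded in the report.
#' @return object of class \code{"assessment"} (a list); see
#'   \code{\link{write_assessment}} for the JSON form.
#' @export
assess_respondent <- function(responses, model, person_id = "respondent") {
  stopifnot(inherits(model, "elmh_model"))
  L <- sum(model$domains$domain_sizes)
  responses <- as.numeric(responses)
  if (length(responses) != L || anyNA(responses)) {
    missing <- if (length(responses) == L) which(is.na(responses))
    else seq_len(L)[-seq_len(min(length(responses), L))]
    stop("input error: incomplete responses; missing item(s) ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  if (any(responses < model$likert_min | responses > model$likert_max))
    stop("input error: responses outside the Likert range", call. = FALSE)
  sums <- drop(domain_sums(matrix(responses, 1), model$domains))
  fscores <- vapply(seq_along(sums), function(d)
    regression_factor_score(d, sums[d], model$regressions), numeric(1))
  mo <- rasch_measure(responses, model$rasch$difficulties,
                      model$rasch$response_min, model$rasch$response_max,
                      model$rasch$dispersion)
  q <- classify_person(mo$measure, mo$outfit,
                       model$cuts["measure"], model$cuts["outfit"])
  advisory <- switch(as.character(q),
                     II = "consultation",
                     III = "no action",
                     "low confidence")
  cnn_outputs <- NULL
  if (!is.null(model$cnn)) {
    pr <- predict(model$cnn, responses)
    cnn_outputs <- drop(pr$outputs)
  }
  structure(list(person_id = person_id,
                 domain_sums = stats::setNames(sums,
                                               model$domains$domain_names),
                 factor_scores = stats::setNames(fscores,
                                                 model$domains$domain_names),
                 measure = mo$measure, outfit = mo$outfit,
                 quadrant = as.character(q),
                 confidence = quadrant_confidence(q),
                 advisory = advisory,
                 cnn_outputs = cnn_outputs),
            class = "assessment")
}

#' @export
print.assessment <- function(x, ...) {
  cat("Assessment report for", x$person_id, "\n")
  cat(sprintf("  measure %.3f logits, outfit %.3f -> quadrant %s (%s)\n",
              x$measure, x$outfit, x$quadrant, x$confidence))
  cat("  advisory:", x$advisory, "\n")
  cat("  factor scores:\n")
  print(round(x$factor_scores, 3))
  if (!is.null(x$cnn_outputs)) {
    cat("  CNN class outputs:\n")
    print(round(x$cnn_outputs, 4))
  }
  invisible(x)
}

#' Write an assessment report to JSON
#'
#' @param assessment an \code{\link{assess_respondent}} report.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
write_assessment <- function(assessment, path) {
  stopifnot(inherits(assessment, "assessment"))
  js <- unclass(assessment)
  js$schema_version <- 1L
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
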