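test_that("expected scores and variances follow the logistic form", {
  ev <- expected_and_variance(0, 0, 1, 5)
  expect_equal(ev$expected, 3.0)
  expect_equal(ev$variance, 4.0)
  ev2 <- expected_and_variance(1, 0, 0, 1)
  expect_equal(ev2$expected, plogis(1), tolerance = 1e-10)
  expect_equal(ev2$variance, plogis(1) * (1 - plogis(1)), tolerance = 1e-10)
  ## saturation
  ev3 <- expected_and_variance(30, 0, 1, 5)
  expect_equal(ev3$expected, 5, tolerance = 1e-9)
  expect_lt(ev3$variance, 1e-9)
  ## the dispersion constant divides the variance, leaving E untouched
  ev4 <- expected_and_variance(0, 0, 1, 5, dispersion = 4)
  expect_equal(ev4$expected, 3.0)
  expect_equal(ev4$variance, 1.0)
  expect_error(expected_and_variance(0, 0, 5, 1), "response_max")
})

test_that("the model family is translation invariant", {
  th <- c(-1, 0, 0.7); dl <- c(-0.5, 0, 0.5, 1)
  a <- expected_and_variance(th, dl, 1, 5)
  b <- expected_and_variance(th + 2.3, dl + 2.3, 1, 5)
  expect_equal(a$expected, b$expected, tolerance = 1e-12)
  expect_equal(a$variance, b$variance, tolerance = 1e-12)
})

test_that("outfit is the mean squared standardized residual", {
  expect_equal(outfit_mnsq(c(3, 3, 3), c(3, 3, 3), c(1, 1, 1)), 0)
  expect_equal(outfit_mnsq(c(5, 1), c(3, 3), c(4, 4)), 1.0)
  ## all standardized residuals +-1
  expect_equal(outfit_mnsq(c(4, 2, 4), c(3, 3, 3), c(1, 1, 1)), 1.0)
  expect_error(outfit_mnsq(1, 1, 0), "positive")
  expect_error(outfit_mnsq(c(1, 2), c(1, 2), 1), "equal length")
})

test_that("a midpoint response against a zero-difficulty item measures zero", {
  mo <- rasch_measure(c(3, 3), c(0, 0), 1, 5)
  expect_equal(mo$measure, 0, tolerance = 1e-6)
})

test_that("higher row sums earn strictly higher measures", {
  coh <- simulate_cohort(simulation_config(n_persons = 80,
                                           aberrant_fraction = 0, seed = 21))
  fit <- fit_rasch(coh$responses, 1, 5)
  ord <- order(rowSums(coh$responses))
  rs <- rowSums(coh$responses)[ord]
  ms <- fit$measures[ord]
  strict <- diff(rs) > 0
  expect_true(all(diff(ms)[strict] > 0))
})

test_that("joint maximum likelihood recovers the generating traits", {
  coh <- simulate_cohort(simulation_config(n_persons = 300, domain_sd = 0,
                                           noise_sd = 0.3,
                                           aberrant_fraction = 0, seed = 14))
  fit <- fit_rasch(coh$responses, 1, 5)
  expect_true(fit$converged)
  expect_gt(cor(fit$measures, coh$true_theta), 0.9)
  expect_gt(cor(fit$difficulties, coh$true_difficulty), 0.9)
  ## anchoring: difficulties centred at zero
  expect_lt(abs(mean(fit$difficulties)), 1e-8)
})

test_that("extreme response rows still receive finite measures", {
  resp <- rbind(rep(1, 10), rep(5, 10),
                matrix(sample(2:4, 80, TRUE), 8, 10))
  fit <- fit_rasch(resp, 1, 5)
  expect_true(all(is.finite(fit$measures)))
  expect_equal(which.min(fit$measures), 1L)
  expect_equal(which.max(fit$measures), 2L)
})

test_that("degenerate all-identical responses are rejected", {
  expect_error(fit_rasch(matrix(3, 5, 5), 1, 5), "degenerate|identical")
})

test_that("rating-scale category curves normalize and cross at thresholds", {
  tau <- c(-1, 0, 1)
  cur <- rating_scale_curves(0, tau, seq(-4, 4, 0.25))
  expect_true(all(abs(rowSums(cur$probabilities) - 1) < 1e-9))
  ## adjacent categories are equiprobable at theta = delta + tau_k
  for (k in seq_along(tau)) {
    p <- rating_scale_curves(0.3, tau, 0.3 + tau[k])$probabilities
    expect_equal(unname(p[1, k]), unname(p[1, k + 1]), tolerance = 1e-9)
  }
})

test_that("category probabilities match a brute-force enumeration", {
  delta <- 0; tau <- c(-1, 0, 1); theta <- 0.4
  ## independent oracle: direct evaluation of the category likelihoods
  psi <- sapply(0:3, function(k)
    exp(sum(rep(theta - delta, k) - tau[seq_len(k)])))
  oracle <- psi / sum(psi)
  got <- rating_scale_curves(delta, tau, theta)$probabilities[1, ]
  expect_equal(unname(got), oracle, tolerance = 1e-12)
})

test_that("conforming cohorts have outfit near its expectation of one", {
  coh <- default_cohort()
  fit <- fit_rasch(coh$responses, 1, 5)
  conforming <- !coh$aberrant_flags
  expect_gt(mean(fit$outfit[conforming]), 0.8)
  expect_lt(mean(fit$outfit[conforming]), 1.2)
  expect_true(all(fit$outfit >= 0))
})

test_that("curves CSV export has one probability column per category", {
  cur <- rating_scale_curves(0, c(-0.5, 0.5), seq(-2, 2, 1))
  path <- file.path(withr::local_tempdir(), "curves.csv")
  write_curves(cur, path)
  df <- read.csv(path)
  expect_identical(names(df), c("measure", "cat0", "cat1", "cat2"))
  expect_equal(rowSums(df[, -1]), rep(1, 5), tolerance = 1e-9)
})
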