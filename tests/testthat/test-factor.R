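test_that("the eigenvalue rule retains factors at the inclusive 1.0 cut", {
  expect_identical(retain_factors(c(3.2, 1.5, 1.0, 0.4)), 3L)
  expect_warning(k <- retain_factors(c(0.9, 0.5)), "criterion")
  expect_identical(k, 0L)
  expect_error(retain_factors(numeric(0)), "non-empty")
  expect_error(retain_factors(c(1, 2)), "descending")
})

test_that("a cohort with 8 independent domain traits retains 8 factors", {
  coh <- simulate_cohort(simulation_config(n_persons = 352, trait_sd = 0,
                                           domain_sd = 1, noise_sd = 0.5,
                                           aberrant_fraction = 0, seed = 3))
  ev <- eigen(cor(coh$responses), symmetric = TRUE, only.values = TRUE)$values
  expect_identical(retain_factors(ev), 8L)
})

test_that("two disjoint latent blocks load on their own factors", {
  coh <- simulate_cohort(simulation_config(n_persons = 300, n_items = 10,
                                           domain_sizes = c(5, 5),
                                           trait_sd = 0, domain_sd = 1.2,
                                           noise_sd = 0.5,
                                           aberrant_fraction = 0, seed = 4))
  efa <- extract_factors(coh$responses, 2)
  top <- apply(abs(efa$loadings), 1, which.max)
  expect_true(all(top[1:5] == top[1]))
  expect_true(all(top[6:10] == top[6]))
  expect_false(top[1] == top[6])
})

test_that("pure-noise items have near-zero communalities", {
  set.seed(8)
  noise <- matrix(sample(1:5, 400 * 12, replace = TRUE), 400, 12)
  efa <- extract_factors(noise, 1)
  expect_true(all(rowSums(efa$loadings^2) < 0.5))
  expect_lt(mean(rowSums(efa$loadings^2)), 0.15)
})

test_that("communality and uniqueness sum to one, before and after rotation", {
  coh <- domain_cohort()
  rot <- extract_factors(coh$responses, 4, rotate = "varimax")
  un <- extract_factors(coh$responses, 4, rotate = "none")
  expect_equal(rowSums(rot$loadings^2) + rot$uniquenesses,
               rep(1, 44), tolerance = 1e-6, ignore_attr = TRUE)
  ## orthogonal rotation leaves the communalities unchanged
  expect_equal(rowSums(rot$loadings^2), rowSums(un$loadings^2),
               tolerance = 1e-8)
})

test_that("Bartlett scores match an independent weighted-least-squares solve", {
  L <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.5,
                0.1, 0.2, 0.8, 0.7, 0.4), 5, 2)
  psi <- c(0.2, 0.3, 0.35, 0.45, 0.5)
  set.seed(6)
  resp <- matrix(rnorm(40 * 5, mean = 3), 40, 5)
  scores <- bartlett_scores(resp, L, psi)
  z <- scale(resp)
  oracle <- t(apply(z, 1, function(zi)
    coef(lm(zi ~ 0 + L, weights = 1 / psi))))
  expect_equal(unname(scores), unname(oracle), tolerance = 1e-10)
})

test_that("Bartlett scoring collapses to the standardized response for a
           single saturated item", {
  resp <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  s <- bartlett_scores(resp, matrix(1), 1)
  expect_equal(drop(s), drop(scale(resp)), ignore_attr = TRUE)
})

test_that("full-cohort Bartlett score columns are centred at zero", {
  coh <- domain_cohort()
  efa <- extract_factors(coh$responses, 8)
  scores <- bartlett_scores(coh$responses, efa)
  expect_true(all(abs(colMeans(scores)) < 1e-8))
})

test_that("zero uniqueness is a singularity error", {
  expect_error(bartlett_scores(matrix(rnorm(20), 10, 2),
                               matrix(c(1, 0, 0, 1), 2, 2), c(0, 0.5)),
               "singularity|uniqueness")
})

test_that("the shipped regression equations evaluate as printed", {
  expect_identical(regression_factor_score(1, 0), -3.2516)
  expect_equal(regression_factor_score(8, 10), 2.1614, tolerance = 1e-10)
  ## zero crossing of the domain-6 mapping
  expect_lt(abs(regression_factor_score(6, 5.4556 / 0.5632)), 1e-3)
  expect_error(regression_factor_score(9, 0), "domain_index")
  ## all printed slopes are positive, so scores rise with the raw sum
  reg <- default_score_regression()
  expect_true(all(reg$slope > 0))
  expect_true(all(diff(regression_factor_score(2, 0:20)) > 0))
})

test_that("sum-to-score regressions recover known coefficients", {
  x <- seq(16, 80, length.out = 50)
  reg <- fit_score_regressions(matrix(x, 50, 1),
                               matrix(-3.2516 + 0.0819 * x, 50, 1))
  expect_equal(reg$intercept[1], -3.2516, tolerance = 1e-10)
  expect_equal(reg$slope[1], 0.0819, tolerance = 1e-10)
  reg3 <- fit_score_regressions(matrix(c(0, 1, 2), 3, 1),
                                matrix(c(1, 3, 5), 3, 1))
  expect_equal(reg3$intercept, 1, tolerance = 1e-12)
  expect_equal(reg3$slope, 2, tolerance = 1e-12)
  expect_error(fit_score_regressions(matrix(1, 5, 1), matrix(1:5, 5, 1)),
               "zero variance")
})

test_that("regression-predicted scores track Bartlett scores per domain", {
  coh <- domain_cohort()
  m <- elmh_model(coh$responses)
  sums <- domain_sums(coh$responses)
  for (d in 1:8) {
    pred <- regression_factor_score(d, sums[, d], m$regressions)
    expect_gt(cor(pred, m$factor_scores[, d]), 0.8)
  }
})

test_that("Bartlett scores are conditionally unbiased in simulation", {
  ## regressing the true factor on the estimated score gives slope near 1
  set.seed(10)
  f <- rnorm(1000)
  lam <- c(0.8, 0.7, 0.6, 0.75, 0.65)
  x <- outer(f, lam) + sapply(lam, function(l) rnorm(1000, 0, sqrt(1 - l^2)))
  s <- bartlett_scores(x, matrix(lam), 1 - lam^2,
                       center = rep(0, 5), scale = rep(1, 5))
  ## conditional unbiasedness: E[score | factor] = factor, i.e. regressing
  ## the estimated score on the true factor has unit slope
  expect_equal(unname(coef(lm(s ~ f))[2]), 1, tolerance = 0.1)
})
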