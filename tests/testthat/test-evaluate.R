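test_that("confusion matrices count (true, predicted) pairs", {
  x <- c("I", "II", "III", "IV", "II")
  cm <- confusion_matrix(x, x)
  expect_equal(unname(diag(cm)), c(1L, 2L, 1L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm2 <- confusion_matrix(c("I", "II", "II"), c("I", "II", "III"))
  expect_identical(cm2["I", "I"], 1L)
  expect_identical(cm2["II", "II"], 1L)
  expect_identical(cm2["II", "III"], 1L)
  expect_error(confusion_matrix(c("I", "II"), "I"), "equal length")
  ## conservation for random labels
  set.seed(1)
  a <- sample(c("I", "II", "III", "IV"), 200, TRUE)
  b <- sample(c("I", "II", "III", "IV"), 200, TRUE)
  expect_identical(sum(confusion_matrix(a, b)), 200L)
})

test_that("accuracy is the trace over the total", {
  expect_equal(accuracy(diag(4)), 1)
  ident <- confusion_matrix(rep("II", 7), rep("II", 7))
  expect_equal(accuracy(ident), 1)
  expect_error(accuracy(matrix(0, 4, 4)), "empty")
  expect_error(accuracy(matrix(1, 2, 3)), "square")
})

test_that("the discriminant baseline separates well-separated Gaussians", {
  set.seed(12)
  f <- rbind(matrix(rnorm(200), 100, 2),
             matrix(rnorm(200, mean = 4), 100, 2))
  lab <- rep(c("a", "b"), each = 100)
  pred <- discriminant_baseline(f, lab)
  expect_gte(mean(pred == lab), 0.99)
})

test_that("duplicate feature columns trigger the ridge path and still
           return predictions", {
  set.seed(13)
  x <- rnorm(60)
  f <- cbind(x, x)
  lab <- rep(c("a", "b"), 30)
  expect_warning(pred <- discriminant_baseline(f, lab), "ridge")
  expect_length(pred, 60)
  expect_false(anyNA(pred))
})

test_that("equal-prior linear scores agree with an independent LDA", {
  skip_if_not_installed("MASS")
  set.seed(14)
  f <- rbind(matrix(rnorm(300), 150, 2),
             matrix(rnorm(300, 1.5), 150, 2))
  lab <- factor(rep(c("a", "b"), each = 150))
  ours <- discriminant_baseline(f, lab)
  theirs <- predict(MASS::lda(f, grouping = lab,
                              prior = c(0.5, 0.5)))$class
  expect_gte(mean(as.character(ours) == as.character(theirs)), 0.99)
})

test_that("with the outfit feature the discriminant sees the misfit classes", {
  coh <- default_cohort()
  m <- default_model()
  lab <- m$classification$quadrant
  f8 <- m$factor_scores
  f9 <- cbind(f8, outfit = m$rasch$outfit)
  a9 <- mean(discriminant_baseline(f9, lab) == lab)
  a8 <- mean(discriminant_baseline(f8, lab) == lab)
  expect_gte(a9, a8)
})

test_that("the trained network keeps pace with the discriminant baseline
           across seeds", {
  ## sanity ordering over 10 simulated cohorts: CNN training accuracy is not
  ## materially below the 8-feature discriminant accuracy
  res <- t(sapply(1:10, function(s) {
    coh <- simulate_cohort(simulation_config(seed = s + 300))
    m <- elmh_model(coh$responses)
    lab <- m$classification$quadrant
    net <- train_cnn(coh$responses, lab,
                     cnn_config(seed = 1, max_epochs = 1500))
    c(cnn = net$training_accuracy,
      lda8 = mean(discriminant_baseline(m$factor_scores, lab) == lab))
  }))
  expect_true(all(res[, "cnn"] >= res[, "lda8"] - 0.05))
})

test_that("sample-size planning reproduces the finite-population formula", {
  expect_identical(required_sample_size(1521), 307L)
  expect_identical(required_sample_size(Inf), 385L)
  expect_lte(required_sample_size(10000, margin = 0.5), 4L)
  ## non-decreasing in population, non-increasing in margin
  pops <- c(200, 500, 1521, 5000, 1e6)
  expect_true(all(diff(sapply(pops, required_sample_size)) >= 0))
  margins <- c(0.02, 0.05, 0.1, 0.2)
  expect_true(all(diff(sapply(margins, function(m)
    required_sample_size(1521, margin = m))) <= 0))
  expect_error(required_sample_size(1521, margin = 0), "margin")
})

test_that("the survey return rate is a plain percentage", {
  expect_equal(round(response_rate(352, 642), 1), 54.8)
  expect_error(response_rate(10, 0), "delivered")
})
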