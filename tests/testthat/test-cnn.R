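test_that("input arrangement rescales and zero-pads row-major", {
  g <- arrange_input(rep(1, 44))
  expect_true(all(g == 0))
  g5 <- arrange_input(rep(5, 44))
  expect_equal(sum(g5 == 1), 44)
  expect_true(all(as.vector(t(g5))[1:44] == 1))   # row-major fill
  expect_true(all(as.vector(t(g5))[45:100] == 0))
  gc <- arrange_input(rep(1:5, length.out = 44))
  expect_equal(gc[1, 1], 0)
  expect_equal(gc[1, 2], 0.25)
  expect_error(arrange_input(rep(1, 43)), "input error")
  expect_error(arrange_input(c(rep(1, 43), 9)), "input error")
})

test_that("parameter accounting matches the per-class geometry", {
  expect_identical(count_parameters(cnn_config()), 108L)
  expect_identical(count_parameters(cnn_config(n_classes = 1)), 27L)
  ## 2-class demonstration layout with an 8-element pooled layer
  expect_identical(count_parameters(cnn_config(n_classes = 2),
                                    pooled_len = 8), 38L)
  expect_error(cnn_config(input_side = 7), "geometry")  # 5 not divisible by 2
})

test_that("forward pass applies sigmoid convolution, max pooling and output", {
  cfg <- cnn_config()
  zero <- elmh:::parameters_from_vector(rep(0, 108), cfg)
  fw <- forward_pass(arrange_input(sample(1:5, 44, TRUE)), zero)
  expect_true(all(abs(fw$conv[[1]] - 0.5) < 1e-12))
  expect_true(all(abs(fw$outputs - 0.5) < 1e-12))
  expect_identical(fw$predicted, 1L)   # tie goes to the lowest class
  ## all-ones window with an all-ones filter pre-activates at 9
  ones <- elmh:::parameters_from_vector(c(rep(1, 9), rep(0, 99)), cfg)
  fw1 <- forward_pass(matrix(1, 10, 10), ones)
  expect_equal(fw1$conv[[1]][1, 1], plogis(9), tolerance = 1e-12)
  ## pooled cells equal the max of their 2x2 conv block
  set.seed(5)
  rnd <- elmh:::parameters_from_vector(runif(108, -0.5, 0.5), cfg)
  fwr <- forward_pass(arrange_input(sample(1:5, 44, TRUE)), rnd)
  for (c in 1:4) for (br in 1:4) for (bc in 1:4)
    expect_equal(fwr$pooled[[c]][br, bc],
                 max(fwr$conv[[c]][(2 * br - 1):(2 * br),
                                   (2 * bc - 1):(2 * bc)]))
})

test_that("forward pass is permutation covariant in the classes", {
  cfg <- cnn_config()
  set.seed(7)
  vec <- runif(108, -0.5, 0.5)
  params <- elmh:::parameters_from_vector(vec, cfg)
  perm <- c(3, 1, 4, 2)
  permuted <- params
  permuted$filters <- params$filters[perm]
  permuted$filter_bias <- params$filter_bias[perm]
  permuted$pool_weights <- params$pool_weights[perm, ]
  permuted$pool_bias <- params$pool_bias[perm]
  g <- arrange_input(sample(1:5, 44, TRUE))
  expect_equal(forward_pass(g, permuted)$outputs,
               forward_pass(g, params)$outputs[perm], tolerance = 1e-12)
})

test_that("the analytic gradient matches central finite differences", {
  cfg <- cnn_config(seed = 2)
  params <- elmh:::with_seed(2, elmh:::init_parameters(cfg))
  set.seed(9)
  feats <- matrix(sample(1:5, 6 * 44, TRUE), 6, 44)
  labs <- c("I", "II", "III", "IV", "II", "III")
  g <- cnn_gradient(params, feats, labs)
  v0 <- elmh:::as_parameter_vector(params)
  h <- 1e-5
  num <- vapply(seq_along(v0), function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (cnn_loss(elmh:::parameters_from_vector(vp, cfg), feats, labs) -
       cnn_loss(elmh:::parameters_from_vector(vm, cfg), feats, labs)) /
      (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - num)) / max(abs(num)), 1e-5)
})

test_that("training is deterministic and separates a separable toy", {
  toy <- rbind(matrix(1, 20, 44), matrix(5, 20, 44))
  labs <- rep(c("III", "II"), each = 20)
  cfg <- cnn_config(max_epochs = 2000, seed = 1)
  net <- train_cnn(toy, labs, cfg)
  expect_equal(net$training_accuracy, 1.0)
  ## final loss never exceeds the initial loss
  expect_lte(net$loss_trace[length(net$loss_trace)], net$loss_trace[1])
  ## determinism: same data and seed give identical parameters
  net2 <- train_cnn(toy, labs, cfg)
  expect_identical(elmh:::as_parameter_vector(net$parameters),
                   elmh:::as_parameter_vector(net2$parameters))
  ## the true class output dominates on every training point
  pr <- predict(net, toy)
  expect_true(all(pr$outputs > 0 & pr$outputs < 1))
  expect_identical(as.character(pr$labels), labs)
  true_idx <- match(labs, net$class_levels)
  other_max <- vapply(seq_len(40), function(i)
    max(pr$outputs[i, -true_idx[i]]), numeric(1))
  expect_true(all(pr$outputs[cbind(seq_len(40), true_idx)] > other_max))
})

test_that("training rejects empty sets and mismatched labels", {
  expect_error(train_cnn(matrix(1, 2, 44), "II"), "labels")
  expect_error(train_cnn(list(), rep("II", 0)), "empty|non-empty|rbind")
})

test_that("parameters round-trip through JSON and bad counts are rejected", {
  cfg <- cnn_config(seed = 3)
  params <- elmh:::with_seed(3, elmh:::init_parameters(cfg))
  path <- file.path(withr::local_tempdir(), "params.json")
  write_cnn_parameters(params, path)
  back <- read_cnn_parameters(path)
  expect_equal(elmh:::as_parameter_vector(back),
               elmh:::as_parameter_vector(params), tolerance = 1e-12)
  ## corrupt the file: drop one parameter
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  js$parameters <- js$parameters[-1]
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_cnn_parameters(path), "107")
})
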