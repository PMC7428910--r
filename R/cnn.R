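#' Configuration of the micro convolutional network
#'
#' Geometry and training settings for the spreadsheet-style network: one
#' 3x3 filter (+ bias) and one fully connected pooled layer (+ bias) per
#' class. With the default 4 classes and a 10x10 input, the chain
#' 10 -> 8 (valid 3x3 convolution, stride 1) -> 4 (2x2 max pooling) gives a
#' 16-element pooled vector and 4 x (10 + 17) = 108 parameters in total.
#'
#' @param n_classes number of output classes.
#' @param input_side side length of the square input grid.
#' @param filter_side convolution filter side (3).
#' @param pool_side max-pooling block side (2); must divide the convolution
#'   output side evenly.
#' @param learning_rate fixed gradient-descent step size.
#' @param max_epochs maximum full-batch epochs.
#' @param seed RNG seed for the uniform(-0.5, 0.5) initialization.
#' @return object of class \code{"cnn_config"}.
#' @export
cnn_config <- function(n_classes = 4, input_side = 10, filter_side = 3,
                       pool_side = 2, learning_rate = 2, max_epochs = 3000,
                       seed = 1) {
  conv_side <- input_side - filter_side + 1L
  if (conv_side < 1)
    stop("geometry error: filter larger than input", call. = FALSE)
  if (conv_side %% pool_side != 0)
    stop("geometry error: pooling blocks of side ", pool_side,
         " do not tile the ", conv_side, "-wide convolution output",
         call. = FALSE)
  if (n_classes < 1 || learning_rate <= 0 || max_epochs < 1)
    stop("invalid cnn_config field", call. = FALSE)
  pooled_side <- conv_side %/% pool_side
  structure(list(n_classes = as.integer(n_classes),
                 input_side = as.integer(input_side),
                 filter_side = as.integer(filter_side),
                 pool_side = as.integer(pool_side),
                 conv_side = as.integer(conv_side),
                 pooled_side = as.integer(pooled_side),
                 pooled_len = as.integer(pooled_side^2),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Total parameter count of the micro network
#'
#' Each class owns a filter (\code{filter_side^2} weights + 1 bias) and a
#' pooled layer (\code{pooled_len} weights + 1 bias):
#' \code{n_classes * (filter_side^2 + 1 + pooled_len + 1)}. The default
#' 4-class, 10x10 geometry gives 4 x (10 + 17) = 108.
#'
#' @param config a \code{\link{cnn_config}}.
#' @param pooled_len override for the pooled-vector length, for layouts whose
#'   pooled layer is not a square grid (e.g. the 2-class demonstration
#'   geometry with an 8-element pooled layer: 2 x (10 + 9) = 38).
#' @return integer parameter count.
#' @examples
#' count_parameters(cnn_config())               # 108
#' count_parameters(cnn_config(n_classes = 1))  # 27
#' @export
count_parameters <- function(config, pooled_len = NULL) {
  stopifnot(inherits(config, "cnn_config"))
  if (is.null(pooled_len)) pooled_len <- config$pooled_len
  as.integer(config$n_classes * (config$filter_side^2 + 1L + pooled_len + 1L))
}

#' Arrange one person's responses into the network's input grid
#'
#' Responses are rescaled to [0, 1] via \code{(v - min) / (max - min)} and
#' placed row-major (left to right, top to bottom) into a square grid; the
#' remaining cells are exactly zero.
#'
#' @param responses numeric vector of item responses (length \code{n_items}).
#' @param likert_min,likert_max the response range used for rescaling.
#' @param input_side grid side length.
#' @param n_items expected number of responses (default 44).
#' @return \code{input_side} x \code{input_side} numeric matrix in [0, 1].
#' @examples
#' g <- arrange_input(rep(1:5, length.out = 44))
#' g[1, 1:2]  # 0.00 0.25
#' @export
arrange_input <- function(responses, likert_min = 1, likert_max = 5,
                          input_side = 10, n_items = 44) {
  responses <- as.numeric(responses)
  if (length(responses) != n_items || anyNA(responses))
    stop("input error: expected ", n_items, " complete responses, got ",
         length(responses) - sum(is.na(responses)), call. = FALSE)
  if (n_items > input_side^2)
    stop("input error: ", n_items, " responses do not fit a ",
         input_side, "x", input_side, " grid", call. = FALSE)
  if (any(responses < likert_min) || any(responses > likert_max))
    stop("input error: responses outside [", likert_min, ", ",
         likert_max, "]", call. = FALSE)
  v <- (responses - likert_min) / (likert_max - likert_min)
  matrix(c(v, rep(0, input_side^2 - n_items)),
         nrow = input_side, byrow = TRUE)
}

## im2col with pool-block-contiguous window ordering: windows are listed
## block by block (pool blocks row-major), the 4 windows of a block
## consecutive, so a conv activation column reshapes to 4 x (n_blocks)
## for pooling. Each row is a filter-side^2 window, column-major flattened.
im2col_grid <- function(grid, cfg) {
  f <- cfg$filter_side; ps <- cfg$pool_side; P <- cfg$pooled_side
  rows <- matrix(0, cfg$pooled_len * ps^2, f^2)
  w <- 0L
  for (br in seq_len(P)) for (bc in seq_len(P))
    for (dr in seq_len(ps)) for (dc in seq_len(ps)) {
      r <- (br - 1L) * ps + dr; cc <- (bc - 1L) * ps + dc
      w <- w + 1L
      rows[w, ] <- as.vector(grid[r:(r + f - 1L), cc:(cc + f - 1L)])
    }
  rows
}

build_batch <- function(features, cfg, likert_min, likert_max, n_items) {
  if (is.matrix(features) && !is.list(features))
    features <- lapply(seq_len(nrow(features)), function(i)
      arrange_input(features[i, ], likert_min, likert_max,
                    cfg$input_side, n_items))
  if (!is.list(features))
    features <- list(arrange_input(features, likert_min, likert_max,
                                   cfg$input_side, n_items))
  X <- do.call(rbind, lapply(features, im2col_grid, cfg = cfg))
  list(X = X, n = length(features))
}

init_parameters <- function(cfg) {
  parameters_from_vector(stats::runif(count_parameters(cfg), -0.5, 0.5), cfg)
}

as_parameter_vector <- function(params) {
  c(unlist(lapply(params$filters, as.vector)), params$filter_bias,
    as.vector(t(params$pool_weights)), params$pool_bias)
}

parameters_from_vector <- function(vec, cfg) {
  nc <- cfg$n_classes; f <- cfg$filter_side; pl <- cfg$pooled_len
  stopifnot(length(vec) == count_parameters(cfg))
  i <- 0L
  filters <- lapply(seq_len(nc), function(c) {
    m <- matrix(vec[i + seq_len(f^2)], f, f); i <<- i + f^2; m
  })
  filter_bias <- vec[i + seq_len(nc)]; i <- i + nc
  pw <- matrix(vec[i + seq_len(nc * pl)], nc, pl, byrow = TRUE)
  i <- i + nc * pl
  pool_bias <- vec[i + seq_len(nc)]
  structure(list(filters = filters, filter_bias = filter_bias,
                 pool_weights = pw, pool_bias = pool_bias,
                 geometry = cfg),
            class = "cnn_parameters")
}

sigmoid <- function(x) stats::plogis(x)

## Vectorized batch forward pass; returns what backprop needs.
batch_forward <- function(X, n, params) {
  cfg <- params$geometry
  nc <- cfg$n_classes; pl <- cfg$pooled_len; bs <- cfg$pool_side^2
  Fmat <- vapply(params$filters, as.vector, numeric(cfg$filter_side^2))
  Z <- X %*% Fmat
  Z <- sweep(Z, 2, params$filter_bias, `+`)
  A <- sigmoid(Z)
  pooled <- vector("list", nc); sel <- vector("list", nc)
  out <- matrix(0, n, nc)
  for (c in seq_len(nc)) {
    Ac <- matrix(A[, c], nrow = bs)          # bs x (n * pl), block-contiguous
    idx <- max.col(t(Ac), ties.method = "first")
    p <- Ac[cbind(idx, seq_len(n * pl))]
    sel[[c]] <- (seq_len(n * pl) - 1L) * bs + idx   # rows of X / A selected
    Pc <- matrix(p, nrow = n, ncol = pl, byrow = TRUE)
    pooled[[c]] <- Pc
    out[, c] <- sigmoid(drop(Pc %*% params$pool_weights[c, ]) +
                          params$pool_bias[c])
  }
  list(A = A, pooled = pooled, sel = sel, outputs = out)
}

#' Forward pass of the micro network for a single input grid
#'
#' Per class: sigmoid of the 3x3 sum-product convolution (plus bias), 2x2
#' non-overlapping max pooling, then a sigmoid fully connected output over
#' the pooled vector. Prediction is the class with the largest output; ties
#' go to the lowest class index.
#'
#' @param grid an \code{\link{arrange_input}} grid.
#' @param params a \code{cnn_parameters} object.
#' @return list with \code{outputs} (per-class sigmoid activations, not
#'   normalized), \code{predicted} (class index), \code{conv} and
#'   \code{pooled} (per-class intermediate matrices).
#' @export
forward_pass <- function(grid, params) {
  cfg <- params$geometry
  if (!is.matrix(grid) || any(dim(grid) != cfg$input_side))
    stop("parameter error: grid must be ", cfg$input_side, "x",
         cfg$input_side, call. = FALSE)
  X <- im2col_grid(grid, cfg)
  bf <- batch_forward(X, 1L, params)
  ## unscramble the block-contiguous activation order into conv matrices
  nc <- cfg$n_classes; P <- cfg$pooled_side; ps <- cfg$pool_side
  conv <- lapply(seq_len(nc), function(c) {
    Cm <- matrix(0, cfg$conv_side, cfg$conv_side)
    w <- 0L
    for (br in seq_len(P)) for (bc in seq_len(P))
      for (dr in seq_len(ps)) for (dc in seq_len(ps)) {
        w <- w + 1L
        Cm[(br - 1L) * ps + dr, (bc - 1L) * ps + dc] <- bf$A[w, c]
      }
    Cm
  })
  pooled <- lapply(seq_len(nc), function(c)
    matrix(bf$pooled[[c]][1, ], P, P, byrow = TRUE))
  outputs <- drop(bf$outputs)
  list(outputs = outputs, predicted = which.max(outputs),
       conv = conv, pooled = pooled)
}

one_hot <- function(labels, levels) {
  idx <- match(as.character(labels), levels)
  if (anyNA(idx)) stop("labels outside the class levels", call. = FALSE)
  T <- matrix(0, length(idx), length(levels))
  T[cbind(seq_along(idx), idx)] <- 1
  T
}

## loss and analytic gradient on a prepared batch
batch_loss_grad <- function(X, n, params, targets, want_grad = TRUE) {
  cfg <- params$geometry
  nc <- cfg$n_classes; pl <- cfg$pooled_len
  bf <- batch_forward(X, n, params)
  err <- bf$outputs - targets
  loss <- sum(err^2) / n
  if (!want_grad) return(list(loss = loss, outputs = bf$outputs))
  gF <- matrix(0, cfg$filter_side^2, nc); gfb <- numeric(nc)
  gW <- matrix(0, nc, pl); gwb <- numeric(nc)
  for (c in seq_len(nc)) {
    o <- bf$outputs[, c]
    gu <- 2 * err[, c] * o * (1 - o) / n          # n
    Pc <- bf$pooled[[c]]
    gW[c, ] <- drop(crossprod(Pc, gu))
    gwb[c] <- sum(gu)
    gp <- outer(gu, params$pool_weights[c, ])     # n x pl
    ga <- as.vector(t(gp))                        # selected-cell order
    a_sel <- bf$A[bf$sel[[c]], c]
    gz <- ga * a_sel * (1 - a_sel)
    gF[, c] <- drop(crossprod(X[bf$sel[[c]], , drop = FALSE], gz))
    gfb[c] <- sum(gz)
  }
  grad <- c(as.vector(gF), gfb, as.vector(t(gW)), gwb)
  list(loss = loss, grad = grad, outputs = bf$outputs)
}

#' Squared-error loss of the micro network
#'
#' Mean over persons of the summed squared difference between the per-class
#' sigmoid outputs and the one-hot encoded labels.
#'
#' @param params a \code{cnn_parameters} object.
#' @param features persons x items response matrix, or a list of input grids.
#' @param labels class labels (factor or character).
#' @param class_levels the ordered class levels; default quadrants I-IV.
#' @param likert_min,likert_max,n_items response layout passed to
#'   \code{\link{arrange_input}} when \code{features} is a response matrix.
#' @return the scalar loss.
#' @export
cnn_loss <- function(params, features, labels,
                     class_levels = c("I", "II", "III", "IV"),
                     likert_min = 1, likert_max = 5, n_items = 44) {
  b <- build_batch(features, params$geometry, likert_min, likert_max, n_items)
  targets <- one_hot(labels, class_levels)
  batch_loss_grad(b$X, b$n, params, targets, want_grad = FALSE)$loss
}

#' Analytic gradient of the micro-network loss
#'
#' Backpropagation through the sigmoid output layer, the max-pooling argmax
#' routing and the sigmoid convolution, in the parameter-vector layout of
#' \code{\link{train_cnn}} (all filters, filter biases, pooled weights,
#' pooled biases). Verifiable against central finite differences.
#'
#' @inheritParams cnn_loss
#' @return numeric gradient vector of length \code{count_parameters}.
#' @export
cnn_gradient <- function(params, features, labels,
                         class_levels = c("I", "II", "III", "IV"),
                         likert_min = 1, likert_max = 5, n_items = 44) {
  b <- build_batch(features, params$geometry, likert_min, likert_max, n_items)
  targets <- one_hot(labels, class_levels)
  batch_loss_grad(b$X, b$n, params, targets)$grad
}

#' Train the micro network by full-batch gradient descent
#'
#' Minimizes the mean squared error between the per-class sigmoid outputs
#' and one-hot labels with a fixed learning rate, from a seeded
#' uniform(-0.5, 0.5) initialization. Training stops at \code{max_epochs} or
#' when the loss improvement falls below 1e-8; the parameters with the lowest
#' loss seen are returned, so the final loss never exceeds the initial one.
#'
#' @param features persons x items response matrix or list of input grids.
#' @param labels per-person class labels (factor or character).
#' @param config a \code{\link{cnn_config}}.
#' @param class_levels ordered class levels; default quadrants I-IV.
#' @param likert_min,likert_max,n_items response layout for
#'   \code{\link{arrange_input}}.
#' @return object of class \code{"micro_cnn"}: \code{parameters},
#'   \code{loss_trace}, \code{config}, \code{class_levels},
#'   \code{training_accuracy}, \code{epochs_run}.
#' @export
train_cnn <- function(features, labels, config = cnn_config(),
                      class_levels = c("I", "II", "III", "IV"),
                      likert_min = 1, likert_max = 5, n_items = 44) {
  stopifnot(inherits(config, "cnn_config"))
  b <- build_batch(features, config, likert_min, likert_max, n_items)
  if (b$n < 1) stop("empty training set", call. = FALSE)
  if (length(labels) != b$n)
    stop("labels must match the number of training examples", call. = FALSE)
  if (length(class_levels) != config$n_classes)
    stop("class_levels must have n_classes entries", call. = FALSE)
  targets <- one_hot(labels, class_levels)
  params <- with_seed(config$seed, init_parameters(config))
  vec <- as_parameter_vector(params)
  trace <- numeric(config$max_epochs + 1L)
  lg <- batch_loss_grad(b$X, b$n, params, targets)
  trace[1L] <- lg$loss
  best_vec <- vec; best_loss <- lg$loss
  epochs <- 0L
  for (e in seq_len(config$max_epochs)) {
    vec <- vec - config$learning_rate * lg$grad
    params <- parameters_from_vector(vec, config)
    lg <- batch_loss_grad(b$X, b$n, params, targets)
    if (!is.finite(lg$loss))
      stop("divergence error: non-finite loss; try a smaller learning_rate",
           call. = FALSE)
    epochs <- e
    trace[e + 1L] <- lg$loss
    if (lg$loss < best_loss) { best_loss <- lg$loss; best_vec <- vec }
    if (abs(trace[e] - lg$loss) < 1e-8) break
  }
  params <- parameters_from_vector(best_vec, config)
  out <- batch_forward(b$X, b$n, params)$outputs
  pred <- class_levels[max.col(out, ties.method = "first")]
  acc <- mean(pred == as.character(labels))
  structure(list(parameters = params, loss_trace = trace[seq_len(epochs + 1L)],
                 config = config, class_levels = class_levels,
                 likert_min = likert_min, likert_max = likert_max,
                 n_items = n_items,
                 training_accuracy = acc, epochs_run = epochs),
            class = "micro_cnn")
}

#' @export
print.micro_cnn <- function(x, ...) {
  cat("Micro convolutional network:",
      count_parameters(x$config), "parameters,",
      x$config$n_classes, "classes\n")
  cat(sprintf("  trained %d epochs, loss %.5f -> %.5f\n", x$epochs_run,
              x$loss_trace[1], x$loss_trace[length(x$loss_trace)]))
  cat(sprintf("  training accuracy %.2f\n", x$training_accuracy))
  invisible(x)
}

#' Predict classes for new respondents
#'
#' @param object a trained \code{micro_cnn}.
#' @param newdata response matrix (persons x items), single response vector,
#'   or list of input grids.
#' @param ... unused.
#' @return list with \code{labels} (factor over the class levels) and
#'   \code{outputs} (persons x classes raw sigmoid activations; not
#'   normalized to sum to 1).
#' @export
predict.micro_cnn <- function(object, newdata, ...) {
  b <- build_batch(newdata, object$config, object$likert_min,
                   object$likert_max, object$n_items)
  out <- batch_forward(b$X, b$n, object$parameters)$outputs
  colnames(out) <- object$class_levels
  labels <- factor(object$class_levels[max.col(out, ties.method = "first")],
                   levels = object$class_levels)
  list(labels = labels, outputs = out)
}

#' Save / load micro-network parameters as JSON
#'
#' The loader rejects files whose parameter count disagrees with the stored
#' geometry.
#'
#' @param params a \code{cnn_parameters} object (or a \code{micro_cnn}, whose
#'   parameters are taken).
#' @param path JSON path.
#' @return \code{write_cnn_parameters}: the path, invisibly;
#'   \code{read_cnn_parameters}: a \code{cnn_parameters} object.
#' @export
write_cnn_parameters <- function(params, path) {
  if (inherits(params, "micro_cnn")) params <- params$parameters
  cfg <- params$geometry
  jsonlite::write_json(
    list(schema_version = 1L,
         geometry = cfg[c("n_classes", "input_side", "filter_side",
                          "pool_side")],
         parameters = as_parameter_vector(params)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cnn_parameters
#' @export
read_cnn_parameters <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- js$geometry
  cfg <- cnn_config(n_classes = g$n_classes, input_side = g$input_side,
                    filter_side = g$filter_side, pool_side = g$pool_side)
  if (length(js$parameters) != count_parameters(cfg))
    stop("parameter file holds ", length(js$parameters),
         " values but the geometry requires ", count_parameters(cfg),
         call. = FALSE)
  parameters_from_vector(js$parameters, cfg)
}
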