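make_fixed_net <- function(value = 0.5) {
  net <- ppd_network(c(2, 2, 1), seed = 1)
  net$weights <- list(matrix(value, 2, 2), matrix(value, 1, 2))
  net$biases <- list(c(0, 0), 0)
  net
}

test_that("the forward pass reproduces hand-evaluated activations", {
  net <- make_fixed_net(0.5)
  fwd <- nn_forward(net, c(1, 1))
  # h_j = sigmoid(0.5 + 0.5) ; y = sigmoid(2 * 0.5 * h)
  expect_equal(as.vector(fwd$activations[[2]]),
               rep(1 / (1 + exp(-1)), 2), tolerance = 1e-6)
  expect_equal(as.vector(fwd$activations[[3]]), 0.6750376,
               tolerance = 1e-6)

  zero <- make_fixed_net(0)
  fwd0 <- nn_forward(zero, c(3, -2))
  expect_equal(as.vector(fwd0$activations[[2]]), c(0.5, 0.5))
  expect_equal(as.vector(fwd0$activations[[3]]), 0.5)

  expect_error(nn_forward(net, c(1, 2, 3)), class = "ppd_shape_error")
})

test_that("dropout-free training-mode forwards equal inference", {
  net <- ppd_network(c(4, 5, 1), dropout_rate = 0, seed = 2)
  x <- matrix(rnorm(12), 3, 4)
  expect_identical(nn_forward(net, x, "train")$activations,
                   nn_forward(net, x, "infer")$activations)
})

test_that("the squared-error loss matches its definition", {
  expect_equal(nn_loss(0.6, 1), 0.08)
  expect_equal(nn_loss(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(nn_loss(1, 0), 0.5)
  expect_error(nn_loss(c(1, 2), 1), class = "ppd_shape_error")
})

test_that("analytic gradients agree with central differences", {
  for (sd in 1:5) {
    net <- withr::with_seed(sd, ppd_network(c(3, 4, 1), init_scale = 0.5))
    x <- withr::with_seed(sd + 100, matrix(rnorm(6), 2, 3))
    d <- matrix(c(1, 0), 2, 1)
    fwd <- nn_forward(net, x, "infer")
    ana <- nn_backward(net, fwd, d)
    num <- numeric_gradients(net, x, d)
    for (g in 1:2) {
      expect_lt(max(rel_err(ana$dW[[g]], num$dW[[g]])), 1e-6)
      expect_lt(max(rel_err(ana$db[[g]], num$db[[g]])), 1e-6)
    }
  }
})

test_that("gradients vanish at a perfect fit and behind dropped units", {
  net <- ppd_network(c(3, 4, 1), seed = 3)
  x <- c(1, 2, 3)
  fwd <- nn_forward(net, x, "infer")
  d <- fwd$activations[[3]]     # y = d exactly
  g <- nn_backward(net, fwd, d)
  expect_true(all(vapply(g$dW, function(w) all(w == 0), logical(1))))
  expect_true(all(vapply(g$db, function(b) all(b == 0), logical(1))))

  dnet <- ppd_network(c(3, 6, 1), dropout_rate = 0.5, seed = 4)
  fwd <- withr::with_seed(11, nn_forward(dnet, x, "train"))
  dropped <- which(fwd$masks[[1]][1, ] == 0)
  expect_gt(length(dropped), 0)
  g <- nn_backward(dnet, fwd, matrix(1, 1, 1))
  # outgoing weights of a dropped unit see a zero activation,
  # incoming weights a zero delta
  expect_true(all(g$dW[[2]][, dropped] == 0))
  expect_true(all(g$dW[[1]][dropped, ] == 0))
  expect_true(all(g$db[[1]][dropped] == 0))
})

test_that("sgd_step applies w - eta * grad exactly", {
  net <- make_fixed_net(1)
  grads <- list(dW = list(matrix(0.5, 2, 2), matrix(0, 1, 2)),
                db = list(c(0, 0), 0))
  up <- sgd_step(net, grads, 0.1)
  expect_equal(up$weights[[1]], matrix(0.95, 2, 2))
  expect_equal(up$weights[[2]], net$weights[[2]])

  same <- sgd_step(net, list(dW = list(matrix(0, 2, 2), matrix(0, 1, 2)),
                             db = list(c(0, 0), 0)), 0.1)
  expect_equal(same$weights, net$weights)

  # two steps at eta equal one step at 2 * eta for fixed gradients
  twice <- sgd_step(sgd_step(net, grads, 0.1), grads, 0.1)
  once <- sgd_step(net, grads, 0.2)
  expect_equal(twice$weights, once$weights)
  expect_error(sgd_step(net, grads, -1), class = "ppd_config_error")
})

test_that("training solves a separable toy problem deterministically", {
  d <- separable_ppd(20)
  # batch 4 gives 200 epochs x 5 updates, enough for full separation
  fit <- train_network(d, epochs = 200, batch_size = 4, seed = 1)
  expect_equal(fit$training_accuracy, 1.0)
  expect_length(fit$loss_history, 200)

  fit2 <- train_network(d, epochs = 200, batch_size = 4, seed = 1)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$network$weights, fit2$network$weights)

  expect_error(train_network(d, epochs = 0), class = "ppd_config_error")
})

test_that("full-batch loss is non-increasing on an easy problem", {
  d <- separable_ppd(16)
  fit <- train_network(d, epochs = 60, batch_size = 16, learning_rate = 0.05,
                       dropout_rate = 0, seed = 5)
  expect_true(all(diff(fit$loss_history) <= 1e-8))
})

test_that("inverted dropout preserves the hidden-activation expectation", {
  net <- ppd_network(c(9, 8, 1), dropout_rate = 0.4, seed = 6)
  x <- rep(c(0.2, 0.8, 0.5), 3)
  infer_h <- nn_forward(net, x, "infer")$activations[[2]]
  draws <- withr::with_seed(7, {
    vapply(1:2000, function(i) {
      nn_forward(net, x, "train")$activations[[2]][1, ]
    }, numeric(8))
  })
  mc_mean <- rowMeans(draws)
  mc_se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(mc_mean - as.vector(infer_h)) <= 3.5 * mc_se))
})

test_that("prediction thresholds probabilities with ties positive", {
  d <- tiny_ppd(16)
  fit <- train_network(d, epochs = 2, seed = 1)
  # an all-zero network outputs exactly 0.5 -> label 1 at the default cut
  fit$network$weights <- lapply(fit$network$weights, function(w) w * 0)
  fit$network$biases <- lapply(fit$network$biases, function(b) b * 0)
  expect_true(all(predict(fit, d, type = "prob") == 0.5))
  expect_true(all(predict(fit, d, type = "class") == 1L))
  expect_true(all(predict(fit, d, type = "class", threshold = 0.51) == 0L))
  expect_error(predict(fit, d[, 1:3]), class = "ppd_schema_error")
})

test_that("network and fit serialization round-trip bit-exactly", {
  net <- ppd_network(c(9, 16, 1), dropout_rate = 0.5, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$weights, net$weights)
  expect_identical(back$biases, net$biases)
  expect_equal(back$layer_sizes, net$layer_sizes)
  expect_equal(back$dropout_rate, 0.5)

  d <- tiny_ppd(20)
  fit <- train_network(d, epochs = 5, seed = 9)
  fpath <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, fpath)
  back <- read_fit(fpath)
  expect_identical(predict(back, d, type = "prob"),
                   predict(fit, d, type = "prob"))
  expect_identical(back$network$weights, fit$network$weights)
})
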