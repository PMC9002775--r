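test_that("zero epochs returns the untouched initialization", {
  d <- separable_xor_free(20, seed = 1)
  net0 <- train_rnn(d$X, d$y, layer_sizes = c(2, 4, 2), epochs = 0, seed = 7)
  ref <- rnn_network(c(2, 4, 2), seed = 7)
  expect_equal(net0$w_plus, ref$w_plus)
  expect_equal(net0$w_minus, ref$w_minus)
})

test_that("analytic gradient matches central differences on a small net", {
  set.seed(5)
  net <- rnn_network(c(3, 4, 2), seed = 5)
  X <- matrix(runif(6 * 3), 6, 3)
  Y <- matrix(0, 6, 2); Y[cbind(1:6, sample(1:2, 6, TRUE))] <- 1
  ga <- rnn_gradient(net, X, Y)
  gn <- rnn_gradient_numerical(net, X, Y)
  for (k in seq_along(ga$w_plus)) {
    expect_lt(max(abs(ga$w_plus[[k]] - gn$w_plus[[k]])) /
                max(abs(gn$w_plus[[k]])), 1e-4)
    expect_lt(max(abs(ga$w_minus[[k]] - gn$w_minus[[k]])) /
                max(abs(gn$w_minus[[k]])), 1e-4)
  }
})

test_that("weights stay nonnegative and identities hold after every epoch", {
  d <- separable_xor_free(60, seed = 2)
  net <- train_rnn(d$X, d$y, layer_sizes = c(2, 5, 2), learning_rate = 0.5,
                   epochs = 30, seed = 3)
  expect_true(all(vapply(net$w_plus, function(w) all(w >= 0), TRUE)))
  expect_true(all(vapply(net$w_minus, function(w) all(w >= 0), TRUE)))
  expect_true(validate_rnn(net, tol = 1e-12))
})

test_that("full-batch loss is non-increasing at a small learning rate", {
  d <- separable_xor_free(60, seed = 6)
  net <- train_rnn(d$X, d$y, layer_sizes = c(2, 5, 2), learning_rate = 0.01,
                   epochs = 60, seed = 1)
  lc <- net$meta$loss_curve
  expect_length(lc, 61)
  expect_true(all(diff(lc) <= 1e-10))
})

test_that("training separates a linearly separable two-class set", {
  d <- separable_xor_free(200, seed = 3)
  net <- train_rnn(d$X, d$y, layer_sizes = c(2, 8, 2), epochs = 200, seed = 1)
  acc <- mean(predict(net, d$X)$label == d$y)
  expect_gte(acc, 0.95)
})

test_that("an absent class warns but does not abort", {
  d <- separable_xor_free(20, seed = 4)
  expect_warning(
    train_rnn(d$X, rep(0L, 20), layer_sizes = c(2, 4, 2), epochs = 1),
    "empty class")
})

test_that("numerical-gradient training takes the same first step as analytic", {
  d <- separable_xor_free(10, seed = 8)
  a <- train_rnn(d$X, d$y, layer_sizes = c(2, 3, 2), epochs = 1,
                 learning_rate = 0.1, seed = 2, gradient = "analytic")
  n <- train_rnn(d$X, d$y, layer_sizes = c(2, 3, 2), epochs = 1,
                 learning_rate = 0.1, seed = 2, gradient = "numerical")
  expect_equal(a$w_plus, n$w_plus, tolerance = 1e-6)
  expect_equal(a$w_minus, n$w_minus, tolerance = 1e-6)
})
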