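test_that("zero network with zero input is everywhere idle", {
  net <- rnn_network(c(2, 2), w_plus = list(matrix(0, 2, 2)),
                     w_minus = list(matrix(0, 2, 2)))
  ss <- solve_steady_state(net)
  expect_equal(ss$f, rep(0, 4))
  expect_true(ss$converged)
})

test_that("single neuron matches the M/M/1 closed form", {
  net <- rnn_network(1, r_output = 1)
  ss <- solve_steady_state(net, list(lambda_plus = 0.3, lambda_minus = 0))
  expect_equal(ss$f, 0.3)
  # with inhibition the denominator grows
  ss2 <- solve_steady_state(net, list(lambda_plus = 0.3, lambda_minus = 0.5))
  expect_equal(ss2$f, 0.3 / 1.5)
})

test_that("layered and damped iterative solvers agree on random nets", {
  for (seed in 1:5) {
    net <- random_ff_net(c(3, 4, 3), seed, w_max = 0.4)
    ext <- random_ext(net, seed + 100)
    a <- solve_steady_state(net, ext, method = "layered")
    b <- solve_steady_state(net, ext, method = "iterative", tol = 1e-12)
    expect_true(a$converged && b$converged)
    expect_equal(a$f, b$f, tolerance = 1e-9)
  }
})

test_that("degenerate neuron (zero service rate, positive drive) errors", {
  net <- rnn_network(c(1, 1), w_plus = list(matrix(0)),
                     w_minus = list(matrix(0)))
  # input neuron has r = 0; excitatory drive makes it unstable
  expect_error(
    solve_steady_state(net, list(lambda_plus = c(0.5, 0),
                                 lambda_minus = c(0, 0))),
    "unstable|degenerate")
})

test_that("saturated networks clip at the cap with a warning", {
  net <- rnn_network(1, r_output = 1)
  expect_warning(
    ss <- solve_steady_state(net, list(lambda_plus = 5, lambda_minus = 0)),
    "saturated")
  expect_equal(ss$f, 1 - 1e-9)
})

test_that("input encoding is linear, zero-preserving, and range-checked", {
  expect_equal(encode_input(rep(0, 5), 9)$lambda_plus, rep(0, 9))
  e <- encode_input(rep(1, 76), 76 + 104, scale = 0.9)
  expect_equal(e$lambda_plus[1:76], rep(0.9, 76))
  expect_equal(e$lambda_plus[77:180], rep(0, 104))
  expect_equal(e$lambda_minus, rep(0, 180))
  set.seed(8)
  v <- runif(10)
  expect_equal(encode_input(v, 10, scale = 0.7)$lambda_plus, 0.7 * v)
  expect_error(encode_input(c(0.5, 1.2), 4), "normaliz")
})

test_that("raising an external excitatory rate never lowers the target's activation", {
  net <- random_ff_net(c(3, 4, 2), seed = 21, w_max = 0.3)
  ext <- random_ext(net, 22)
  base <- solve_steady_state(net, ext)$f
  for (l in 1:3) {
    bumped <- ext
    bumped$lambda_plus[l] <- bumped$lambda_plus[l] + 0.1
    f2 <- solve_steady_state(net, bumped)$f
    expect_gte(f2[l], base[l])
  }
})

test_that("prediction picks the maximal output and breaks ties low", {
  # output weights feed only class-0 neuron -> label 0
  wp <- list(matrix(0.5, 2, 3), cbind(c(1, 1, 1), 0, 0, 0))
  wm <- list(matrix(0, 2, 3), matrix(0, 3, 4))
  net <- rnn_network(c(2, 3, 4), w_plus = wp, w_minus = wm)
  p <- predict(net, c(0.8, 0.8))
  expect_equal(p$label, 0L)
  # symmetric weights into outputs 1 and 2 -> exact tie, choose class 1
  wp2 <- list(matrix(0.5, 2, 3), cbind(0, c(1, 1, 1), c(1, 1, 1), 0))
  net2 <- rnn_network(c(2, 3, 4), w_plus = wp2, w_minus = wm)
  p2 <- predict(net2, c(0.8, 0.8))
  expect_equal(p2$activations[1, 2], p2$activations[1, 3])
  expect_equal(p2$label, 1L)
  expect_true(all(p2$activations >= 0 & p2$activations < 1))
})

test_that("prediction on a seeded trained net reproduces the frozen fixture", {
  d <- separable_xor_free(40, seed = 9)
  net <- train_rnn(d$X, d$y, layer_sizes = c(2, 6, 2), epochs = 50, seed = 4)
  p <- predict(net, rbind(c(0.2, 0.8), c(0.8, 0.2)))
  expect_equal(p$label, c(0L, 1L))
})
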