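test_that("convolution shape arithmetic rejects oversized kernels", {
  expect_error(cnn_summary(c(5, 5, 1), list(
    layer_spec("conv2d", filters = 2, kernel = c(8, 8)))), "kernel")
})

test_that("parameter counts follow the conv and dense closed forms", {
  s <- cnn_summary(c(10, 10, 3), list(
    layer_spec("conv2d", filters = 4, kernel = c(3, 3)),
    layer_spec("flatten"),
    layer_spec("dense", units = 5)))
  expect_equal(s$parameters, c(3 * 3 * 3 * 4 + 4, 0, 8 * 8 * 4 * 5 + 5))
  expect_equal(s$output_shape, c("8 x 8 x 4", "256", "5"))
  expect_equal(attr(s, "total_parameters"), sum(s$parameters))
})

test_that("channel attention scales channels by sigmoid of pooled means", {
  set.seed(3)
  X <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  # zero fc -> att = 0.5 everywhere -> output halves the input
  z <- gap_channel_attention(X, list(weights = matrix(0, 3, 3)))
  expect_equal(z$att, rep(0.5, 3))
  expect_equal(z$output, X / 2)
  # strongly positive diagonal on positive-mean channels saturates att -> 1
  Xp <- abs(X) + 1
  s <- gap_channel_attention(Xp, list(weights = diag(1e4, 3)))
  expect_equal(s$output, Xp, tolerance = 1e-6)
  # random case: independent elementwise recomputation
  W <- matrix(rnorm(9), 3); b <- rnorm(3)
  g <- gap_channel_attention(X, list(weights = W, bias = b))
  att <- 1 / (1 + exp(-(W %*% apply(X, 1, mean) + b)))
  for (i in 1:3)
    expect_equal(g$output[i, , ], X[i, , ] * att[i], tolerance = 1e-12)
  expect_true(all(g$att > 0 & g$att < 1))
  expect_true(all(abs(g$output) <= abs(X)))
  expect_true(all(sign(g$output) == sign(X) | X == 0))
})

test_that("cosine transform matches direct evaluation of the sum", {
  # constant signal concentrates on the zeroth coefficient
  f <- dct_forward(rep(3, 8), norm = "none")
  expect_equal(f[1], 24)
  expect_equal(f[-1], rep(0, 7), tolerance = 1e-12)
  # unit impulse at i = 0, L = 4: f_k = cos(pi k / 8)
  f2 <- dct_forward(c(1, 0, 0, 0), norm = "none")
  expect_equal(f2, cos(pi * (0:3) / 8), tolerance = 1e-14)
})

test_that("orthonormal cosine transform round-trips and preserves energy", {
  set.seed(9)
  x <- rnorm(64)
  f <- dct_forward(x)
  expect_lt(max(abs(dct_inverse(f) - x)), 1e-10)
  expect_equal(sum(f^2), sum(x^2), tolerance = 1e-12)      # Parseval
  # unnormalized variant round-trips through its weighted inverse
  expect_lt(max(abs(dct_inverse(dct_forward(x, "none"), "none") - x)), 1e-10)
  # 2-D separable inverse undoes forward along both axes
  M <- matrix(rnorm(6 * 8), 6, 8)
  coef <- apply(t(apply(M, 1, dct_forward)), 2, dct_forward)
  expect_lt(max(abs(dct_inverse_2d(coef) - M)), 1e-10)
})

test_that("unknown baseline kinds error and deep backends signal skip", {
  feats <- featurize_segments(tiny_segments(c(3, 3, 3, 3), seed = 1))
  expect_error(train_baseline("svm", feats), "valid kinds")
  expect_error(train_baseline("cnn", feats), class = "backend_unavailable")
  expect_error(train_baseline("resnet", feats), class = "backend_unavailable")
})

test_that("extremely randomized trees separate the synthetic classes", {
  segs <- generate_dataset(synthetic_config(c(100, 100, 100, 100), seed = 11))
  feats <- featurize_segments(segs)
  fit <- train_baseline("ert", feats, seed = 11)
  expect_gte(fit$report$overall$accuracy, 0.90)
  expect_s3_class(fit$report, "evaluation_report")
})
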