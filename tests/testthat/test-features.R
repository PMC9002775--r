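test_that("segmentation cuts whole windows and drops the remainder", {
  labels <- rep(0L, 10)
  m <- matrix(rnorm(19 * 1500), 19)
  expect_length(segment_recording(m, 500, labels), 3)
  expect_length(segment_recording(matrix(rnorm(19 * 499), 19), 500, labels), 0)
  segs <- segment_recording(matrix(rnorm(19 * 2750), 19), 500, labels)
  expect_length(segs, 5)
  expect_equal(dim(segs[[1]]$data), c(19, 500))
  expect_equal(vapply(segs, function(s) s$t_start, 1), 0:4)
  # conservation: windows * fs never exceeds the sample count
  expect_lte(length(segs) * 500, 2750)
})

test_that("segmentation validates channel count and label coverage", {
  m <- matrix(rnorm(5 * 1000), 5)
  expect_error(segment_recording(m, 500, rep(0, 2), expected_channels = 19),
               "expected 19")
  expect_error(segment_recording(m, 500, labels = 0L), "label sequence")
})

test_that("channel dropping removes named rows, warns on absent, keeps order", {
  m <- matrix(seq_len(21 * 10), 21, 10,
              dimnames = list(standard_channels(21), NULL))
  d <- drop_channels(m)
  expect_equal(nrow(d), 19)
  expect_equal(rownames(d), setdiff(standard_channels(21), c("Cz", "Pz")))
  # already-dropped record: warning, unchanged
  expect_warning(d2 <- drop_channels(d), "not present")
  expect_identical(d2, d)
  # empty list is the identity
  expect_identical(drop_channels(m, character(0)), m)
})

test_that("per-channel moments match closed forms", {
  # constant channel: degenerate convention [0, 0, 0, c]
  seg <- matrix(7, 1, 500)
  expect_equal(unname(extract_features(seg)), c(0, 0, 0, 7))
  # alternating -1/+1: mean 0, population std 1, skew 0, excess kurt -2
  alt <- matrix(rep(c(-1, 1), 250), 1, 500)
  expect_equal(unname(extract_features(alt)), c(1, -2, 0, 0))
  # 19-channel segment yields the 76-dimensional vector
  seg19 <- tiny_segments(c(1, 0, 0, 0), seed = 2)[[1]]
  expect_length(extract_features(seg19), 76)
})

test_that("moment extraction agrees with direct formula evaluation", {
  set.seed(13)
  x <- rnorm(500, mean = 2, sd = 3)
  v <- unname(extract_features(matrix(x, 1)))
  m <- mean(x); c2 <- mean((x - m)^2)
  expect_equal(v, c(sqrt(c2), mean((x - m)^4) / c2^2 - 3,
                    mean((x - m)^3) / c2^1.5, m), tolerance = 1e-12)
})

test_that("channel permutation permutes the feature blocks identically", {
  set.seed(4)
  m <- matrix(rnorm(5 * 100), 5, dimnames = list(paste0("c", 1:5), NULL))
  perm <- c(3, 1, 5, 2, 4)
  v <- extract_features(m)
  vp <- extract_features(m[perm, ])
  blocks <- function(v) split(unname(v), rep(seq_len(5), each = 4))
  expect_equal(blocks(vp), unname(blocks(v)[perm]), ignore_attr = TRUE)
})

test_that("NaN input errors and names the offending channel", {
  m <- matrix(rnorm(2 * 100), 2, dimnames = list(c("Fp1", "Fp2"), NULL))
  m[2, 50] <- NaN
  expect_error(extract_features(m), "Fp2")
})

test_that("min-max normalization maps the fitted range onto [0, 1]", {
  set.seed(6)
  X <- matrix(runif(50, -10, 10), 10, 5)
  X[, 3] <- 4.2                       # constant feature
  p <- fit_normalizer(X)
  N <- apply_normalizer(p, X)
  expect_equal(apply(N[, -3], 2, min), rep(0, 4))
  expect_equal(apply(N[, -3], 2, max), rep(1, 4))
  expect_equal(N[, 3], rep(0, 10))    # constant maps to 0, no div error
  mid <- (p$x_min + p$x_max) / 2
  expect_equal(unname(apply_normalizer(p, mid)[-3]), rep(0.5, 4))
  # out-of-range test values are clipped
  expect_equal(unname(apply_normalizer(p, p$x_max + 100)),
               c(1, 1, 0, 1, 1))
  # idempotent on already-normalized training data
  p2 <- fit_normalizer(N)
  expect_equal(apply_normalizer(p2, N), N)
})

test_that("feature tables carry provenance and labels", {
  segs <- tiny_segments(c(2, 1, 0, 1), seed = 3)
  df <- featurize_segments(segs)
  expect_equal(nrow(df), 4)
  expect_equal(df$label, c(0L, 0L, 1L, 3L))
  expect_length(eegrnn:::feature_columns(df), 76)
})
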