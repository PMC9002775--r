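#' Layer specification for the convolutional-network calculator
#'
#' @param kind One of `"conv2d"`, `"dropout"`, `"flatten"`, `"dense"`.
#' @param filters,kernel For `conv2d`: filter count and kernel `c(h, w)`
#'   (valid padding, stride 1, bias).
#' @param units For `dense`: output width (bias included).
#' @param rate Dropout rate (bookkeeping only; contributes no parameters).
#' @return Object of class `layer_spec`.
#' @export
layer_spec <- function(kind = c("conv2d", "dropout", "flatten", "dense"),
                       filters = NULL, kernel = NULL, units = NULL,
                       rate = NULL) {
  kind <- match.arg(kind)
  if (kind == "conv2d") stopifnot(filters >= 1, length(kernel) == 2,
                                  all(kernel >= 1))
  if (kind == "dense") stopifnot(units >= 1)
  structure(list(kind = kind, filters = filters, kernel = kernel,
                 units = units, rate = rate), class = "layer_spec")
}

#' The study's reference CNN layer stack
#'
#' Three valid-padded convolutions (32 filters 8x8, 64 filters 5x5,
#' 64 filters 3x3) each followed by dropout, then flatten and two dense
#' layers (32 and 4 units). Dropout rates are configurable; they carry no
#' parameters.
#'
#' @param conv_dropout,dense_dropout Dropout rates after conv / dense.
#' @return List of [layer_spec()] objects.
#' @export
reference_cnn_layers <- function(conv_dropout = 0.25, dense_dropout = 0.5) {
  list(
    layer_spec("conv2d", filters = 32, kernel = c(8, 8)),
    layer_spec("dropout", rate = conv_dropout),
    layer_spec("conv2d", filters = 64, kernel = c(5, 5)),
    layer_spec("dropout", rate = conv_dropout),
    layer_spec("conv2d", filters = 64, kernel = c(3, 3)),
    layer_spec("dropout", rate = conv_dropout),
    layer_spec("flatten"),
    layer_spec("dense", units = 32),
    layer_spec("dropout", rate = dense_dropout),
    layer_spec("dense", units = 4))
}

#' Per-layer output shapes and parameter counts of a CNN
#'
#' Pure integer arithmetic, no learning framework: a valid-padded stride-1
#' convolution maps spatial dim `n` to `n - k + 1` and costs
#' `kh * kw * in_channels * filters + filters` parameters; a dense layer
#' costs `in * units + units`; dropout and flatten cost nothing.
#'
#' @param input_shape `c(height, width, channels)` of the input tensor.
#' @param layers List of [layer_spec()]; default [reference_cnn_layers()].
#' @return Data frame with columns `layer`, `output_shape` (string),
#'   `parameters`; total parameter count as attribute `total_parameters`.
#' @examples
#' cnn_summary()  # 19 x 500 x 1 input, reference stack
#' @export
cnn_summary <- function(input_shape = c(19, 500, 1),
                        layers = reference_cnn_layers()) {
  shape <- as.integer(input_shape)   # h, w, c  (or flat length after flatten)
  flat <- FALSE
  rows <- lapply(layers, function(l) {
    params <- 0L
    if (l$kind == "conv2d") {
      if (flat) stop("conv2d after flatten")
      if (any(l$kernel > shape[1:2]))
        stop("kernel ", paste(l$kernel, collapse = "x"),
             " larger than input ", paste(shape[1:2], collapse = "x"))
      params <- prod(l$kernel) * shape[3] * l$filters + l$filters
      shape <<- c(shape[1:2] - l$kernel + 1L, l$filters)
    } else if (l$kind == "flatten") {
      shape <<- prod(shape); flat <<- TRUE
    } else if (l$kind == "dense") {
      if (!flat) { shape <<- prod(shape); flat <<- TRUE }
      params <- shape * l$units + l$units
      shape <<- l$units
    }
    data.frame(layer = l$kind,
               output_shape = paste(shape, collapse = " x "),
               parameters = as.numeric(params))
  })
  out <- do.call(rbind, rows)
  attr(out, "total_parameters") <- sum(out$parameters)
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Channel attention by global average pooling
#'
#' Computes per-channel attention weights `att = sigmoid(W gap(X) + b)`
#' from the channels' spatial means and rescales each channel by its
#' weight. Attention values lie strictly in (0, 1), so channel signs are
#' preserved and magnitudes never grow.
#'
#' @param X Array `c(channels, h, w)` (a matrix is treated as
#'   `channels x w` with `h = 1`).
#' @param fc List with `weights` (`C x C` matrix) and optional `bias`
#'   (length `C`).
#' @return List with `output` (same shape as `X`), `att`, `gap`.
#' @export
gap_channel_attention <- function(X, fc) {
  if (is.matrix(X)) dim(X) <- c(nrow(X), 1, ncol(X))
  stopifnot(length(dim(X)) == 3)
  C <- dim(X)[1]
  W <- as.matrix(fc$weights)
  b <- fc$bias %||% numeric(C)
  stopifnot(all(dim(W) == c(C, C)), length(b) == C)
  gap <- apply(X, 1, mean)
  att <- sigmoid(drop(W %*% gap) + b)
  out <- X * att   # leading dimension recycles per channel
  list(output = out, att = att, gap = gap)
}

#' Discrete cosine transform (type II) and its inverse
#'
#' Forward: `f[k] = s(k) * sum_i x[i] * cos(pi * k * (i + 1/2) / L)`.
#' With `norm = "none"` the raw cosine sums are returned; with
#' `norm = "ortho"` the scaling `s(0) = sqrt(1/L)`, `s(k>0) = sqrt(2/L)`
#' makes the transform orthonormal so [dct_inverse()] reconstructs the
#' signal exactly.
#'
#' @param x Numeric vector (length `L >= 1`).
#' @param norm `"ortho"` (default) or `"none"`.
#' @return Coefficient vector of length `L`.
#' @export
dct_forward <- function(x, norm = c("ortho", "none")) {
  norm <- match.arg(norm)
  L <- length(x)
  stopifnot(L >= 1)
  k <- 0:(L - 1); i <- 0:(L - 1)
  Cmat <- cos(pi * outer(k, i + 0.5) / L)
  f <- drop(Cmat %*% x)
  if (norm == "ortho") f <- f * c(sqrt(1 / L), rep(sqrt(2 / L), L - 1))
  f
}

#' @rdname dct_forward
#' @param coef Coefficients from [dct_forward()] (same `norm`).
#' @export
dct_inverse <- function(coef, norm = c("ortho", "none")) {
  norm <- match.arg(norm)
  L <- length(coef)
  k <- 0:(L - 1); i <- 0:(L - 1)
  Cmat <- cos(pi * outer(k, i + 0.5) / L)   # orthogonal rows under s(k)
  if (norm == "ortho") {
    drop(t(Cmat) %*% (coef * c(sqrt(1 / L), rep(sqrt(2 / L), L - 1))))
  } else {
    # invert the raw sums: x = C^T D f with D the orthonormal weights squared
    w <- c(1 / L, rep(2 / L, L - 1))
    drop(t(Cmat) %*% (coef * w))
  }
}

#' Two-dimensional separable inverse DCT
#'
#' Applies the 1-D inverse transform along rows then columns, the separable
#' form used to map 2-D cosine coefficients back to a signal block.
#'
#' @param coef Matrix of 2-D DCT coefficients.
#' @param norm Passed to [dct_inverse()].
#' @return Reconstructed matrix of the same size.
#' @export
dct_inverse_2d <- function(coef, norm = "ortho") {
  step1 <- apply(coef, 2, dct_inverse, norm = norm)
  t(apply(step1, 1, dct_inverse, norm = norm))
}

#' Train a comparison baseline
#'
#' `"ert"` fits extremely randomized trees through \pkg{ranger}
#' (`splitrule = "extratrees"`, whole-sample training without bootstrap,
#' one random cut-point per candidate feature) on the feature table and
#' reports held-out metrics in the same schema as the RNN path. The
#' trainable deep baselines (`"cnn"`, `"resnet"`) require an optional
#' deep-learning backend and signal a condition of class
#' `backend_unavailable` when none is present.
#'
#' @param kind `"ert"`, `"cnn"`, or `"resnet"`.
#' @param features Feature data frame from [featurize_segments()] (must
#'   contain a `label` column).
#' @param train_fraction,seed Split controls (see [split_train_test()]).
#' @param num_trees Trees in the ensemble (ERT).
#' @return List with `model`, `report` (an `evaluation_report`), and the
#'   split indices.
#' @export
train_baseline <- function(kind, features, train_fraction = 0.9, seed = 1,
                           num_trees = 300) {
  valid <- c("ert", "cnn", "resnet")
  if (!kind %in% valid)
    stop("unknown baseline '", kind, "'; valid kinds: ",
         paste(valid, collapse = ", "))
  if (kind %in% c("cnn", "resnet")) {
    cond <- structure(
      class = c("backend_unavailable", "error", "condition"),
      list(message = paste0("baseline '", kind, "' needs an optional ",
                            "deep-learning backend; the shape/parameter ",
                            "calculator (cnn_summary) and feature operators ",
                            "(gap_channel_attention, dct_forward) are ",
                            "available without one"),
           call = sys.call()))
    stop(cond)
  }
  stopifnot("label" %in% colnames(features))
  split <- split_train_test(nrow(features), train_fraction, seed = seed)
  fc <- feature_columns(features)
  df <- data.frame(label = factor(features$label, levels = 0:3),
                   features[, fc, drop = FALSE])
  fit <- ranger::ranger(label ~ ., data = df[split$train, ],
                        num.trees = num_trees, splitrule = "extratrees",
                        num.random.splits = 1, replace = FALSE,
                        sample.fraction = 1, seed = seed)
  pred <- predict(fit, df[split$test, ])$predictions
  report <- evaluation_metrics(confusion(
    features$label[split$test], as.integer(as.character(pred))))
  report$metadata <- list(model = "ert", seed = seed,
                          train_fraction = train_fraction,
                          num_trees = num_trees)
  list(model = fit, report = report, split = split)
}
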