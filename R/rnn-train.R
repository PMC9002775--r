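#' Squared-error loss of a random neural network on a labeled batch
#'
#' @param net An `rnn_network`.
#' @param X Matrix of normalized features, one sample per row.
#' @param Y One-hot target matrix (`nrow(X)` x output width).
#' @param scale Input encoding scale.
#' @return Mean over samples of half the squared error between output
#'   activations and targets.
#' @export
rnn_loss <- function(net, X, Y, scale = 0.9) {
  fwd <- rnn_forward(net, X, scale)
  out <- fwd$f[[length(fwd$f)]]
  mean(0.5 * rowSums((out - Y)^2))
}

#' Analytic gradient of the batch loss
#'
#' Reverse-mode differentiation through the layered steady-state equations.
#' Each activation is `f = lambda_plus / (r + lambda_minus)`; a weight
#' `w[i, j]` (either sign) affects the loss through three channels: the
#' excitatory numerator of neuron `j`, the inhibitory denominator of `j`,
#' and the firing rate `r[i]` of its source neuron, which by the rate/weight
#' identity is the sum of all of `i`'s outgoing weights. Activations pinned
#' at the cap contribute zero derivative.
#'
#' @inheritParams rnn_loss
#' @return List with `w_plus`, `w_minus` (per-layer gradient blocks) and
#'   `loss`.
#' @export
rnn_gradient <- function(net, X, Y, scale = 0.9) {
  fwd <- rnn_forward(net, X, scale)
  f <- fwd$f; den <- fwd$den
  M <- length(f)
  ns <- nrow(X)
  out <- f[[M]]
  loss <- mean(0.5 * rowSums((out - Y)^2))

  mask <- lapply(f, function(m) (m < 1 - CLIP_EPS) * 1)
  G <- vector("list", M)
  G[[M]] <- ((out - Y) / ns) * mask[[M]]
  for (k in M:2) {
    A <- G[[k]] / den[[k]]
    G[[k - 1]] <- (A %*% t(net$w_plus[[k - 1]]) -
                     (A * f[[k]]) %*% t(net$w_minus[[k - 1]])) * mask[[k - 1]]
  }

  gp <- vector("list", M - 1)
  gm <- vector("list", M - 1)
  for (k in seq_len(M - 1)) {
    A <- G[[k + 1]] / den[[k + 1]]
    h <- colSums(G[[k]] * f[[k]] / den[[k]])    # firing-rate channel
    ones <- rep(1, net$layer_sizes[k + 1])
    gp[[k]] <- crossprod(f[[k]], A) - h %o% ones
    gm[[k]] <- -crossprod(f[[k]], A * f[[k + 1]]) - h %o% ones
  }
  list(w_plus = gp, w_minus = gm, loss = loss)
}

#' Central-difference gradient (independent check)
#'
#' Perturbs every weight in turn, rebuilding the firing rates from the
#' perturbed weights before each forward pass, so the numerical gradient
#' sees exactly the dependence structure the analytic gradient claims.
#'
#' @inheritParams rnn_loss
#' @param eps Perturbation step.
#' @return List with per-layer gradient blocks `w_plus`, `w_minus`.
#' @export
rnn_gradient_numerical <- function(net, X, Y, scale = 0.9, eps = 1e-5) {
  loss_at <- function(net2) {
    net2$r <- network_firing_rates(net2)
    rnn_loss(net2, X, Y, scale)
  }
  diff_block <- function(which, k) {
    W <- net[[which]][[k]]
    g <- W * 0
    for (idx in seq_along(W)) {
      np <- net; np[[which]][[k]][idx] <- W[idx] + eps
      nm <- net; nm[[which]][[k]][idx] <- max(W[idx] - eps, 0)
      step <- np[[which]][[k]][idx] - nm[[which]][[k]][idx]
      g[idx] <- (loss_at(np) - loss_at(nm)) / step
    }
    g
  }
  nk <- length(net$w_plus)
  list(w_plus = lapply(seq_len(nk), function(k) diff_block("w_plus", k)),
       w_minus = lapply(seq_len(nk), function(k) diff_block("w_minus", k)))
}

#' Train a random neural network by projected gradient descent
#'
#' Full-batch (or mini-batch) gradient descent on the squared error against
#' one-hot targets. After every update, negative weight components are
#' clipped to zero (weight rates must stay nonnegative) and the firing rates
#' are recomputed from the weights, so the rate/weight and
#' probability-conservation identities hold throughout training.
#'
#' @param features Matrix or data frame of normalized features in `[0, 1]`,
#'   one sample per row.
#' @param labels Integer class labels, `0`-based, `< layer_sizes` last entry.
#' @param layer_sizes Layer widths; first must equal `ncol(features)`, last
#'   is the number of classes. Default `c(ncol, 100, 80, 4)`.
#' @param learning_rate Positive step size (default 0.2).
#' @param epochs Number of passes over the data (0 returns the untouched
#'   initialization).
#' @param batch_size `NULL` for full batch, else mini-batch size.
#' @param gradient `"analytic"` (default) or `"numerical"` (central
#'   differences; only sensible for tiny networks).
#' @param scale Input encoding scale.
#' @param r_output Firing rate of the output neurons.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param tol Early-stopping tolerance on the drop in full-batch loss
#'   (0 disables).
#' @param verbose Print the loss every 10 epochs.
#' @return A trained `rnn_network`; `meta` carries `loss_curve` (full-batch
#'   loss before training and after every epoch), `scale`, and the
#'   configuration.
#' @export
train_rnn <- function(features, labels, layer_sizes = NULL,
                      learning_rate = 0.2, epochs = 100, batch_size = NULL,
                      gradient = c("analytic", "numerical"), scale = 0.9,
                      r_output = 1, seed = 1, tol = 0, verbose = FALSE) {
  gradient <- match.arg(gradient)
  X <- as.matrix(features)
  labels <- as.integer(labels)
  if (is.null(layer_sizes)) layer_sizes <- c(ncol(X), 100, 80, 4)
  stopifnot(learning_rate > 0, epochs >= 0,
            ncol(X) == layer_sizes[1],
            all(labels >= 0), all(labels < layer_sizes[length(layer_sizes)]))
  n_classes <- layer_sizes[length(layer_sizes)]
  present <- tabulate(labels + 1L, nbins = n_classes)
  if (any(present == 0))
    warning("training data has empty class(es): ",
            paste(which(present == 0) - 1L, collapse = ", "))
  Y <- matrix(0, nrow(X), n_classes)
  Y[cbind(seq_len(nrow(X)), labels + 1L)] <- 1

  net <- rnn_network(layer_sizes, r_output = r_output, seed = seed)
  grad_fun <- if (gradient == "analytic") rnn_gradient else
    function(net, X, Y, scale) {
      g <- rnn_gradient_numerical(net, X, Y, scale)
      g$loss <- rnn_loss(net, X, Y, scale)
      g
    }

  loss_curve <- rnn_loss(net, X, Y, scale)
  if (!is.finite(loss_curve)) stop("non-finite initial loss")
  if (epochs > 0) for (ep in seq_len(epochs)) {
    idx_sets <- if (is.null(batch_size)) list(seq_len(nrow(X))) else {
      perm <- sample.int(nrow(X))
      split(perm, ceiling(seq_along(perm) / batch_size))
    }
    for (idx in idx_sets) {
      g <- grad_fun(net, X[idx, , drop = FALSE], Y[idx, , drop = FALSE], scale)
      if (!is.finite(g$loss))
        stop("non-finite loss at epoch ", ep,
             "; reduce the learning rate or input scale")
      for (k in seq_along(net$w_plus)) {
        net$w_plus[[k]] <- pmax(net$w_plus[[k]] - learning_rate * g$w_plus[[k]], 0)
        net$w_minus[[k]] <- pmax(net$w_minus[[k]] - learning_rate * g$w_minus[[k]], 0)
      }
      net$r <- network_firing_rates(net)
    }
    loss_curve <- c(loss_curve, rnn_loss(net, X, Y, scale))
    if (verbose && ep %% 10 == 0)
      message("epoch ", ep, " loss ", signif(loss_curve[ep + 1], 6))
    if (tol > 0 && ep > 1 &&
        abs(loss_curve[ep] - loss_curve[ep + 1]) < tol) break
  }

  net$meta <- c(net$meta, list(
    scale = scale, learning_rate = learning_rate, epochs = epochs,
    batch_size = batch_size, gradient = gradient,
    loss_curve = loss_curve, final_loss = loss_curve[length(loss_curve)],
    n_classes = n_classes))
  net
}
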