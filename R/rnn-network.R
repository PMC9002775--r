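#' @useDynLib eegrnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm sd predict filter
#' @importFrom utils read.csv write.csv modifyList
NULL

CLIP_EPS <- 1e-9

#' Construct a feedforward Gelenbe random neural network
#'
#' A random neural network (RNN) is a network of spiking neurons holding
#' nonnegative integer potentials. Neurons exchange excitatory (+1) and
#' inhibitory (-1) Poisson spike streams; an excited neuron (potential > 0)
#' fires at rate `r[l]`, routing each spike to neuron `j` as excitatory with
#' probability `p_plus[l, j]`, inhibitory with probability `p_minus[l, j]`,
#' or out of the network with probability `d[l]`. The nonnegative weight
#' rates are `w_plus[l, j] = r[l] * p_plus[l, j]` and
#' `w_minus[l, j] = r[l] * p_minus[l, j]`, and for every neuron with
#' `d[l] < 1` the firing rate satisfies
#' `r[l] = (1 - d[l])^-1 * sum_j (w_plus[l, j] + w_minus[l, j])`,
#' so that routing probabilities sum to one.
#'
#' The classifier configuration is strictly layered: weights run only from
#' each layer to the next, the departure probability is 1 on the output
#' layer (spikes leave the network) and 0 elsewhere, and output neurons get
#' a fixed firing rate `r_output` since they have no outgoing weights.
#'
#' @param layer_sizes Integer vector of layer widths, e.g. `c(76, 100, 80, 4)`.
#' @param w_plus,w_minus Optional lists of per-layer nonnegative weight
#'   matrices (`layer_sizes[k] x layer_sizes[k + 1]`). When omitted, weights
#'   are drawn uniformly on `[0, 1/fan_out]`.
#' @param r_output Firing rate assigned to output neurons (default 1).
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `rnn_network` with elements `layer_sizes`,
#'   `w_plus`, `w_minus` (per-layer blocks), `r`, `d`, `n_neurons`,
#'   `layer_of` (layer index of each neuron, 1-based), and `meta`.
#' @examples
#' net <- rnn_network(c(4, 6, 2), seed = 1)
#' net$n_neurons
#' @export
rnn_network <- function(layer_sizes, w_plus = NULL, w_minus = NULL,
                        r_output = 1, seed = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 1, all(layer_sizes >= 1), r_output > 0)
  n_layers <- length(layer_sizes)
  if (!is.null(seed)) set.seed(seed)

  init_block <- function(k) {
    fan_out <- layer_sizes[k + 1]
    matrix(runif(layer_sizes[k] * fan_out, 0, 1 / fan_out),
           layer_sizes[k], fan_out)
  }
  if (is.null(w_plus))  w_plus  <- lapply(seq_len(n_layers - 1), init_block)
  if (is.null(w_minus)) w_minus <- lapply(seq_len(n_layers - 1), init_block)
  stopifnot(length(w_plus) == n_layers - 1, length(w_minus) == n_layers - 1)
  if (n_layers > 1) for (k in seq_len(n_layers - 1)) {
    w_plus[[k]] <- as.matrix(w_plus[[k]])
    w_minus[[k]] <- as.matrix(w_minus[[k]])
    stopifnot(
      all(dim(w_plus[[k]]) == c(layer_sizes[k], layer_sizes[k + 1])),
      all(dim(w_minus[[k]]) == dim(w_plus[[k]])),
      all(w_plus[[k]] >= 0), all(w_minus[[k]] >= 0)
    )
  }

  n <- sum(layer_sizes)
  layer_of <- rep(seq_len(n_layers), layer_sizes)
  d <- ifelse(layer_of == n_layers, 1, 0)

  net <- structure(
    list(layer_sizes = layer_sizes, w_plus = w_plus, w_minus = w_minus,
         d = d, n_neurons = n, layer_of = layer_of,
         meta = list(seed = seed, r_output = r_output)),
    class = "rnn_network")
  net$r <- network_firing_rates(net)
  net
}

# r for every neuron: Eq-8 algebra on the layer blocks; output neurons
# (d = 1, no outgoing weights) take the fixed r_output.
network_firing_rates <- function(net) {
  n_layers <- length(net$layer_sizes)
  r <- numeric(0)
  for (k in seq_len(n_layers - 1)) {
    out_sum <- rowSums(net$w_plus[[k]]) + rowSums(net$w_minus[[k]])
    r <- c(r, out_sum)  # d = 0 on non-output layers
  }
  c(r, rep(net$meta$r_output, net$layer_sizes[n_layers]))
}

#' Firing rates from weight rates and departure probabilities
#'
#' Inverts the weight/rate relation of the random neural network:
#' `r[l] = (1 - d[l])^-1 * sum_j (w_plus[l, j] + w_minus[l, j])`, which makes
#' the routing probabilities `p_plus = w_plus / r`, `p_minus = w_minus / r`
#' together with `d` sum to one for every firing neuron.
#'
#' @param w_plus,w_minus N x N nonnegative weight-rate matrices.
#' @param d Length-N departure probabilities in `[0, 1]`.
#' @return Length-N nonnegative firing rates. A neuron with `d[l] = 1` and no
#'   outgoing weight gets rate 0 (it never routes spikes internally).
#' @examples
#' firing_rates_from_weights(matrix(2), matrix(1), 0)    # 3
#' firing_rates_from_weights(matrix(2), matrix(1), 0.5)  # 6
#' @export
firing_rates_from_weights <- function(w_plus, w_minus, d) {
  w_plus <- as.matrix(w_plus); w_minus <- as.matrix(w_minus)
  stopifnot(all(w_plus >= 0), all(w_minus >= 0),
            all(d >= 0), all(d <= 1),
            nrow(w_plus) == length(d), all(dim(w_plus) == dim(w_minus)))
  out_sum <- rowSums(w_plus) + rowSums(w_minus)
  if (any(d >= 1 & out_sum > 0))
    stop("neuron with departure probability 1 cannot have outgoing weights ",
         "(probability conservation would be violated)")
  r <- numeric(length(d))
  live <- d < 1
  r[live] <- out_sum[live] / (1 - d[live])
  r
}

#' Routing probabilities of a random neural network
#'
#' @param w_plus,w_minus N x N weight-rate matrices.
#' @param r Length-N firing rates.
#' @return List with matrices `p_plus` and `p_minus`; rows of
#'   zero-firing-rate neurons are zero.
#' @export
routing_probabilities <- function(w_plus, w_minus, r) {
  scale <- ifelse(r > 0, 1 / r, 0)
  list(p_plus = w_plus * scale, p_minus = w_minus * scale)
}

# Assemble full N x N weight matrices from the per-layer blocks.
full_weight_matrices <- function(net) {
  n <- net$n_neurons
  wp <- matrix(0, n, n); wm <- matrix(0, n, n)
  offs <- c(0, cumsum(net$layer_sizes))
  for (k in seq_along(net$w_plus)) {
    rows <- (offs[k] + 1):offs[k + 1]
    cols <- (offs[k + 1] + 1):offs[k + 2]
    wp[rows, cols] <- net$w_plus[[k]]
    wm[rows, cols] <- net$w_minus[[k]]
  }
  list(w_plus = wp, w_minus = wm)
}

# Indices (1-based) of neurons in layer k.
layer_indices <- function(net, k) {
  offs <- c(0, cumsum(net$layer_sizes))
  (offs[k] + 1):offs[k + 1]
}

#' Validate random-neural-network invariants
#'
#' Checks nonnegativity, the probability-conservation identity
#' `sum_j (p_plus + p_minus) + d = 1` for every firing neuron, and the
#' firing-rate/weight consistency for every neuron with `d < 1`.
#'
#' @param net An `rnn_network`.
#' @param tol Numerical tolerance (default `1e-12`).
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_rnn <- function(net, tol = 1e-12) {
  stopifnot(inherits(net, "rnn_network"))
  w <- full_weight_matrices(net)
  if (any(w$w_plus < 0) || any(w$w_minus < 0)) stop("negative weight rate")
  if (any(net$r < 0)) stop("negative firing rate")
  if (any(net$d < 0 | net$d > 1)) stop("departure probability outside [0,1]")
  out_sum <- rowSums(w$w_plus) + rowSums(w$w_minus)
  live <- net$d < 1
  bad <- live & abs(net$r - out_sum / (1 - net$d)) > tol * pmax(1, net$r)
  if (any(bad)) stop("firing rate inconsistent with weights for neuron(s) ",
                     paste(which(bad), collapse = ", "))
  p <- routing_probabilities(w$w_plus, w$w_minus, net$r)
  fire <- net$r > 0
  cons <- rowSums(p$p_plus) + rowSums(p$p_minus) + net$d
  bad <- fire & live & abs(cons - 1) > tol
  if (any(bad)) stop("probability conservation violated for neuron(s) ",
                     paste(which(bad), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.rnn_network <- function(x, ...) {
  cat("Feedforward random neural network\n")
  cat("  layers:", paste(x$layer_sizes, collapse = "-"),
      " (", x$n_neurons, "neurons )\n")
  cat("  output firing rate:", x$meta$r_output, "\n")
  if (!is.null(x$meta$epochs))
    cat("  trained:", x$meta$epochs, "epochs, final loss",
        signif(x$meta$final_loss, 6), "\n")
  invisible(x)
}
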