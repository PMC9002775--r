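#' Discrete-event simulation of the spiking network
#'
#' Runs the random neural network as the continuous-time Markov chain it
#' models: neurons hold integer potentials, external excitatory/inhibitory
#' spikes arrive as Poisson streams, and excited neurons fire at their rate,
#' routing spikes by the network's probabilities or departing with
#' probability `d`. The empirical fraction of time each neuron spends
#' excited (`potential > 0`) converges to the analytic steady-state
#' activation, which makes the simulator an independent oracle for
#' [solve_steady_state()].
#'
#' An initial fraction of events is discarded as burn-in (the chain starts
#' empty); the remaining time is split into batches whose means provide a
#' standard error that accounts for autocorrelation.
#'
#' @param net An `rnn_network`.
#' @param ext Exogenous input (see [encode_input()]), or `NULL`.
#' @param n_events Number of events to simulate (default `1e6`).
#' @param seed Integer seed (the simulator has its own RNG stream).
#' @param n_batches Number of batches for the standard-error estimate.
#' @param burn_in Fraction of events discarded before measuring.
#' @return List with `busy_fraction`, `se` (per-neuron standard errors),
#'   `total_time` (measured simulated time), `events`.
#' @examples
#' net <- rnn_network(c(2, 2), seed = 1)
#' ext <- encode_input(c(0.3, 0.6), net$n_neurons)
#' sim <- simulate_network(net, ext, n_events = 1e4, seed = 2)
#' @export
simulate_network <- function(net, ext = NULL, n_events = 1e6, seed = 1,
                             n_batches = 100, burn_in = 0.1) {
  stopifnot(inherits(net, "rnn_network"), n_events >= 1)
  n <- net$n_neurons
  if (is.null(ext))
    ext <- list(lambda_plus = numeric(n), lambda_minus = numeric(n))
  validate_rnn(net, tol = 1e-8)
  w <- full_weight_matrices(net)
  simulate_network_cpp(w$w_plus, w$w_minus, net$r,
                       ext$lambda_plus, ext$lambda_minus,
                       as.numeric(n_events), as.integer(seed),
                       as.integer(n_batches), burn_in)
}
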