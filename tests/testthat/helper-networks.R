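# Shared fixture builders (everything generated in code, seeded).

# Random feedforward net with weights scaled to keep activations stable.
random_ff_net <- function(layer_sizes, seed, w_max = 0.5) {
  set.seed(seed)
  blocks <- function() lapply(seq_len(length(layer_sizes) - 1), function(k)
    matrix(runif(layer_sizes[k] * layer_sizes[k + 1], 0, w_max),
           layer_sizes[k], layer_sizes[k + 1]))
  rnn_network(layer_sizes, w_plus = blocks(), w_minus = blocks())
}

random_ext <- function(net, seed, max_rate = 0.8) {
  set.seed(seed)
  n_in <- net$layer_sizes[1]
  encode_input(runif(n_in, 0.05, max_rate), net$n_neurons, scale = 1)
}

# Random stable case: the steady-state product form (and hence the
# simulator comparison) holds only while every activation stays below 1,
# so the external drive is shrunk deterministically until the net is
# unsaturated.
stable_ff_case <- function(sizes, net_seed, ext_seed, w_max = 0.5,
                           cap = 0.95) {
  net <- random_ff_net(sizes, seed = net_seed, w_max = w_max)
  ext <- random_ext(net, ext_seed)
  repeat {
    f <- suppressWarnings(solve_steady_state(net, ext))$f
    if (max(f) <= cap) break
    ext$lambda_plus <- ext$lambda_plus * 0.8
  }
  list(net = net, ext = ext)
}

# Two-feature, two-class linearly separable set.
separable_xor_free <- function(n = 200, seed = 3) {
  set.seed(seed)
  X <- rbind(cbind(runif(n / 2, 0, 0.45), runif(n / 2, 0.55, 1)),
             cbind(runif(n / 2, 0.55, 1), runif(n / 2, 0, 0.45)))
  list(X = X, y = rep(0:1, each = n / 2))
}

tiny_segments <- function(n_per_class = c(5, 5, 5, 5), seed = 1) {
  generate_dataset(synthetic_config(n_per_class, seed = seed))
}
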