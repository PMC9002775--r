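#' Encode a normalized feature vector as exogenous spike rates
#'
#' Each normalized feature drives one input-layer neuron: its value, scaled
#' by `scale`, becomes the neuron's external excitatory Poisson arrival rate.
#' External inhibitory rates are zero. The scale (default 0.9) keeps input
#' activations strictly below one.
#'
#' @param features Numeric vector in `[0, 1]`, one entry per input neuron.
#' @param n_neurons Total neuron count of the target network.
#' @param scale Positive multiplier applied to every feature.
#' @param tol Tolerance for the `[0, 1]` range check.
#' @return List with `lambda_plus` and `lambda_minus`, both length
#'   `n_neurons`; nonzero only on the first `length(features)` entries.
#' @export
encode_input <- function(features, n_neurons, scale = 0.9, tol = 1e-8) {
  features <- as.numeric(features)
  stopifnot(scale > 0, n_neurons >= length(features))
  if (any(features < -tol | features > 1 + tol))
    stop("features must lie in [0, 1]; apply min-max normalization first ",
         "(see fit_normalizer/apply_normalizer)")
  lp <- numeric(n_neurons)
  lp[seq_along(features)] <- scale * pmin(pmax(features, 0), 1)
  list(lambda_plus = lp, lambda_minus = numeric(n_neurons))
}

#' Solve the steady state of a random neural network
#'
#' Computes the stationary activation `f[l]` of every neuron, i.e. the
#' probability that its potential is positive. The fixed point is
#' `f[l] = (lambda_plus_int[l] + Lambda_plus[l]) /
#'         (r[l] + lambda_minus_int[l] + Lambda_minus[l])`
#' with internal arrival rates
#' `lambda_plus_int[l] = sum_j f[j] * w_plus[j, l]` and
#' `lambda_minus_int[l] = sum_j f[j] * w_minus[j, l]`, capped at
#' `1 - 1e-9` (an activation pinned at the cap indicates a neuron driven
#' past saturation). For a strictly layered network the solution is obtained
#' exactly in a single topological pass; otherwise a damped fixed-point
#' iteration is used.
#'
#' @param net An `rnn_network`.
#' @param ext Exogenous input as returned by [encode_input()], or `NULL` for
#'   no external arrivals.
#' @param tol Convergence tolerance on the fixed-point residual.
#' @param max_iter Iteration cap for the damped solver.
#' @param method `"auto"` (layered pass for layered nets), `"layered"`, or
#'   `"iterative"`.
#' @param damping Damping factor of the iterative solver in `(0, 1]`.
#' @return Object of class `rnn_steady_state`: `f` (activations), `residual`
#'   (max absolute fixed-point violation), `converged`, `iterations`.
#' @examples
#' net <- rnn_network(c(2, 3, 2), seed = 1)
#' ext <- encode_input(c(0.2, 0.7), net$n_neurons)
#' solve_steady_state(net, ext)$f
#' @export
solve_steady_state <- function(net, ext = NULL, tol = 1e-10, max_iter = 10000,
                               method = c("auto", "layered", "iterative"),
                               damping = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(net, "rnn_network"), tol > 0)
  n <- net$n_neurons
  if (is.null(ext))
    ext <- list(lambda_plus = numeric(n), lambda_minus = numeric(n))
  stopifnot(length(ext$lambda_plus) == n, length(ext$lambda_minus) == n,
            all(ext$lambda_plus >= 0), all(ext$lambda_minus >= 0))

  if (method == "iterative") {
    return(solve_iterative(net, ext, tol, max_iter, damping))
  }
  solve_layered(net, ext, tol)
}

clip_activation <- function(f) pmin(f, 1 - CLIP_EPS)

activation_ratio <- function(num, den, what = "neuron") {
  bad <- den <= 0 & num > 0
  if (any(bad))
    stop("unstable/degenerate ", what, " ", paste(which(bad), collapse = ", "),
         ": zero total service/inhibition rate with nonzero excitatory input")
  f <- ifelse(den > 0, num / den, 0)
  clip_activation(f)
}

# Exact one-pass solver for the layered topology: each layer's activations
# depend only on the previous layer's, so evaluating layers in order solves
# the fixed point with no iteration.
solve_layered <- function(net, ext, tol) {
  n_layers <- length(net$layer_sizes)
  f <- numeric(net$n_neurons)
  clipped <- FALSE
  for (k in seq_len(n_layers)) {
    idx <- layer_indices(net, k)
    lam_p <- ext$lambda_plus[idx]
    lam_m <- ext$lambda_minus[idx]
    if (k > 1) {
      prev <- layer_indices(net, k - 1)
      lam_p <- lam_p + drop(crossprod(net$w_plus[[k - 1]], f[prev]))
      lam_m <- lam_m + drop(crossprod(net$w_minus[[k - 1]], f[prev]))
    }
    num <- lam_p
    den <- net$r[idx] + lam_m
    f[idx] <- activation_ratio(num, den)
    clipped <- clipped || any(num / pmax(den, .Machine$double.xmin) >
                                1 - CLIP_EPS & den > 0)
  }
  if (clipped)
    warning("activation(s) clipped at 1 - 1e-9: network is saturated")
  res <- steady_state_residual(net, ext, f)
  structure(list(f = f, residual = res, converged = res <= tol,
                 iterations = 1L),
            class = "rnn_steady_state")
}

solve_iterative <- function(net, ext, tol, max_iter, damping) {
  stopifnot(damping > 0, damping <= 1)
  w <- full_weight_matrices(net)
  f <- numeric(net$n_neurons)
  pinned <- integer(net$n_neurons)
  res <- Inf
  for (it in seq_len(max_iter)) {
    num <- ext$lambda_plus + drop(crossprod(w$w_plus, f))
    den <- net$r + ext$lambda_minus + drop(crossprod(w$w_minus, f))
    target <- activation_ratio(num, den)
    res <- max(abs(f - target))
    f_new <- (1 - damping) * f + damping * target
    pinned <- ifelse(f_new >= 1 - CLIP_EPS - tol, pinned + 1L, 0L)
    f <- f_new
    if (res <= tol) break
  }
  if (any(pinned > 10))
    warning("neuron(s) pinned at the activation cap for > 10 iterations: ",
            paste(which(pinned > 10), collapse = ", "))
  structure(list(f = f, residual = steady_state_residual(net, ext, f),
                 converged = res <= tol, iterations = it),
            class = "rnn_steady_state")
}

#' Fixed-point residual of a candidate steady state
#'
#' @param net An `rnn_network`; `ext` exogenous input; `f` candidate
#'   activation vector.
#' @return Max absolute violation of the capped fixed-point equation.
#' @export
steady_state_residual <- function(net, ext, f) {
  w <- full_weight_matrices(net)
  num <- ext$lambda_plus + drop(crossprod(w$w_plus, f))
  den <- net$r + ext$lambda_minus + drop(crossprod(w$w_minus, f))
  target <- ifelse(den > 0, pmin(num / den, 1 - CLIP_EPS), 0)
  max(abs(f - target))
}

#' @export
print.rnn_steady_state <- function(x, ...) {
  cat("Random-neural-network steady state\n")
  cat("  neurons:", length(x$f),
      " residual:", format(x$residual, digits = 3),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Classify feature vectors with a trained random neural network
#'
#' Feeds each normalized 76-feature vector into the input layer as external
#' excitatory rates, solves the steady state, and assigns the class whose
#' output neuron has the largest activation; ties break toward the lowest
#' class index.
#'
#' @param object A trained `rnn_network` whose output width equals the number
#'   of classes.
#' @param features Numeric vector (one sample) or matrix/data frame with one
#'   sample per row, values in `[0, 1]`.
#' @param scale Input encoding scale (default taken from training metadata,
#'   else 0.9).
#' @param ... Unused.
#' @return List with `label` (integer class codes, `0`-based) and
#'   `activations` (matrix of output-neuron activations, one row per sample).
#' @export
predict.rnn_network <- function(object, features, scale = NULL, ...) {
  if (is.null(scale)) scale <- object$meta$scale %||% 0.9
  X <- if (is.null(dim(features))) matrix(as.numeric(features), nrow = 1)
       else as.matrix(features)
  stopifnot(ncol(X) == object$layer_sizes[1])
  fwd <- rnn_forward(object, X, scale)
  act <- fwd$f[[length(fwd$f)]]
  label <- max.col(act, ties.method = "first") - 1L
  list(label = label, activations = act)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized layered forward pass over a batch: X is n_samples x n_inputs in
# [0, 1]. Returns per-layer activation matrices f[[k]] and denominators
# den[[k]] (r + total inhibitory arrivals), used by both predict and the
# analytic gradient.
rnn_forward <- function(net, X, scale = 0.9) {
  n_layers <- length(net$layer_sizes)
  f <- vector("list", n_layers)
  den <- vector("list", n_layers)
  ns <- nrow(X)
  r1 <- net$r[layer_indices(net, 1)]
  num <- scale * X
  den[[1]] <- matrix(r1, ns, length(r1), byrow = TRUE)
  if (any(r1 <= 0 & apply(num > 0, 2, any)))
    stop("input neuron with zero firing rate receives excitatory input")
  f[[1]] <- clip_activation(ifelse(den[[1]] > 0, num / den[[1]], 0))
  if (n_layers > 1) for (k in 2:n_layers) {
    lam_p <- f[[k - 1]] %*% net$w_plus[[k - 1]]
    lam_m <- f[[k - 1]] %*% net$w_minus[[k - 1]]
    rk <- net$r[layer_indices(net, k)]
    den[[k]] <- sweep(lam_m, 2, rk, "+")
    bad <- den[[k]] <= 0 & lam_p > 0
    if (any(bad)) stop("unstable/degenerate neuron in layer ", k)
    f[[k]] <- clip_activation(ifelse(den[[k]] > 0, lam_p / den[[k]], 0))
  }
  list(f = f, den = den)
}
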