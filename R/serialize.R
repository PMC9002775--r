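#' Save a random neural network to JSON
#'
#' Stores the layer layout, weight blocks, firing rates, departure
#' probabilities, training metadata, and (optionally) the fitted
#' normalization parameters in one self-contained JSON file.
#'
#' @param net An `rnn_network`.
#' @param path Output path.
#' @param normalizer Optional `minmax_params` to bundle with the model.
#' @return `path`, invisibly.
#' @export
save_rnn <- function(net, path, normalizer = NULL) {
  stopifnot(inherits(net, "rnn_network"))
  obj <- list(
    format = "eegrnn/rnn-v1",
    layer_sizes = net$layer_sizes,
    w_plus = net$w_plus, w_minus = net$w_minus,
    r = net$r, d = net$d,
    meta = net$meta[!vapply(net$meta, is.null, TRUE)])
  if (!is.null(normalizer))
    obj$normalizer <- list(x_min = normalizer$x_min,
                           x_max = normalizer$x_max)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a random neural network saved by [save_rnn()]
#'
#' @param path JSON model file.
#' @return List with `net` (`rnn_network`) and `normalizer`
#'   (`minmax_params` or `NULL`).
#' @export
load_rnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "eegrnn/rnn-v1"))
    stop("not an eegrnn model file: ", path)
  wp <- lapply(obj$w_plus, as.matrix)
  wm <- lapply(obj$w_minus, as.matrix)
  net <- rnn_network(obj$layer_sizes, w_plus = wp, w_minus = wm,
                     r_output = obj$meta$r_output %||% 1)
  net$meta <- c(net$meta[c("seed", "r_output")],
                obj$meta[setdiff(names(obj$meta), c("seed", "r_output"))])
  norm <- NULL
  if (!is.null(obj$normalizer))
    norm <- structure(list(x_min = obj$normalizer$x_min,
                           x_max = obj$normalizer$x_max),
                      class = "minmax_params")
  list(net = net, normalizer = norm)
}
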