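# Rate-based feedforward networks used as both teacher and student.
# A network is a list of weight matrices (fan_out x fan_in), no biases;
# every layer (including the output) applies the activation elementwise.

#' Construct a random layered feedforward network
#'
#' Builds a fully connected, bias-free, rate-based network.  `layer_sizes`
#' gives the input dimension followed by the neuron count of each layer, so
#' `c(12, 20, 10)` is a 12-input network with a 20-neuron hidden layer and a
#' 10-neuron output layer (440 weights).  Weights are drawn from the Xavier
#' (Glorot) distribution: uniform on
#' \eqn{\pm\sqrt{6/(\mathrm{fan\_in}+\mathrm{fan\_out})}} by default, or the
#' normal variant with variance \eqn{2/(\mathrm{fan\_in}+\mathrm{fan\_out})}.
#'
#' @param layer_sizes integer vector, length >= 2: input dimension then
#'   neurons per layer.
#' @param activation `"sigmoid"` (logistic at every layer, including the
#'   output) or `"linear"`.
#' @param seed non-negative integer; the draw is deterministic given the seed.
#' @param init `"uniform"` (default) or `"normal"` Xavier variant.
#' @return an object of class `layered_network`: list with `layer_sizes`,
#'   `activation`, `weights` (list of fan_out x fan_in matrices), `n_par`.
#' @examples
#' net <- make_layered_network(c(12, 20, 10), "sigmoid", seed = 1)
#' net$n_par # 440
#' @export
make_layered_network <- function(layer_sizes,
                                 activation = c("sigmoid", "linear"),
                                 seed = 0L,
                                 init = c("uniform", "normal")) {
  activation <- match.arg(activation)
  init <- match.arg(init)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) {
    stop("`layer_sizes` needs at least an input dimension and one layer")
  }
  if (any(layer_sizes <= 0L)) {
    stop("invalid architecture: all layer sizes must be positive")
  }
  weights <- with_seed(seed, {
    lapply(seq_len(length(layer_sizes) - 1L), function(k) {
      fan_in <- layer_sizes[k]
      fan_out <- layer_sizes[k + 1L]
      if (init == "uniform") {
        lim <- sqrt(6 / (fan_in + fan_out))
        matrix(runif(fan_out * fan_in, -lim, lim), fan_out, fan_in)
      } else {
        matrix(rnorm(fan_out * fan_in, 0, sqrt(2 / (fan_in + fan_out))),
               fan_out, fan_in)
      }
    })
  })
  structure(
    list(layer_sizes = layer_sizes,
         activation = activation,
         weights = weights,
         n_par = sum(vapply(weights, length, 1L)),
         seed = seed,
         init = init),
    class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("Layered feedforward network (%s, no biases)\n", x$activation))
  cat("  architecture:", paste(x$layer_sizes, collapse = " -> "), "\n")
  cat("  parameters:  ", x$n_par, "\n")
  invisible(x)
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Forward pass through a layered network
#'
#' Computes the firing rates \eqn{r = \sigma(W u)} layer by layer
#' (\eqn{\sigma} the logistic function for sigmoid networks, identity for
#' linear networks; applied at every layer including the output).
#'
#' @param net a `layered_network`.
#' @param input a numeric vector of length equal to the input dimension, or
#'   a matrix with one input per column.
#' @return output rates: a vector (vector input) or matrix (matrix input).
#' @export
forward <- function(net, input) {
  vec <- is.null(dim(input))
  x <- if (vec) matrix(input, ncol = 1L) else input
  if (nrow(x) != net$layer_sizes[1L]) {
    stop(sprintf("input dimension %d does not match network input size %d",
                 nrow(x), net$layer_sizes[1L]))
  }
  for (W in net$weights) {
    x <- W %*% x
    if (net$activation == "sigmoid") x <- logistic(x)
  }
  if (vec) drop(x) else x
}

# Forward pass keeping all layer activations (for backprop).  Returns list
# of matrices: acts[[1]] is the input, acts[[k+1]] layer k's rates.
forward_activations <- function(net, input_mat) {
  acts <- vector("list", length(net$weights) + 1L)
  acts[[1L]] <- input_mat
  x <- input_mat
  for (k in seq_along(net$weights)) {
    x <- net$weights[[k]] %*% x
    if (net$activation == "sigmoid") x <- logistic(x)
    acts[[k + 1L]] <- x
  }
  acts
}

#' Flatten network weights into a single vector
#'
#' The flattening order is fixed and documented: layer-major, then row-major
#' within each weight matrix.  `unflatten_weights()` is its exact inverse.
#'
#' @param net a `layered_network`, or a list of weight matrices.
#' @return numeric vector of length `n_par`.
#' @export
flatten_weights <- function(net) {
  ws <- if (inherits(net, "layered_network")) net$weights else net
  unlist(lapply(ws, function(W) as.vector(t(W))), use.names = FALSE)
}

#' Rebuild weight matrices from a flat vector
#'
#' @param w numeric vector as produced by [flatten_weights()].
#' @param net the `layered_network` supplying the shapes.
#' @return a list of weight matrices.
#' @export
unflatten_weights <- function(w, net) {
  sizes <- net$layer_sizes
  out <- vector("list", length(net$weights))
  pos <- 0L
  for (k in seq_along(out)) {
    fan_in <- sizes[k]
    fan_out <- sizes[k + 1L]
    n <- fan_in * fan_out
    out[[k]] <- matrix(w[(pos + 1L):(pos + n)], fan_out, fan_in, byrow = TRUE)
    pos <- pos + n
  }
  if (pos != length(w)) stop("weight vector length does not match network")
  out
}

# Replace a network's weights with a flat vector (returns a new network).
set_weights <- function(net, w) {
  net$weights <- unflatten_weights(w, net)
  net
}

#' Generate a suite of random input vectors
#'
#' Draws `n_inputs` vectors whose components are i.i.d. standard normal
#' ("unit-Gaussian firing rates").  The suite is generated once per task and
#' held fixed for the whole simulation.
#'
#' @param n_inputs number of input vectors (>= 1).
#' @param dim dimension of each vector (>= 1).
#' @param seed non-negative integer.
#' @return object of class `input_suite`: list with `inputs` (dim x n_inputs
#'   matrix, one input per column), `n_inputs`, `dim`.
#' @export
make_input_suite <- function(n_inputs, dim, seed = 0L) {
  stopifnot(n_inputs >= 1, dim >= 1)
  inputs <- with_seed(seed, matrix(rnorm(dim * n_inputs), dim, n_inputs))
  structure(list(inputs = inputs, n_inputs = as.integer(n_inputs),
                 dim = as.integer(dim), seed = seed),
            class = "input_suite")
}

#' @export
print.input_suite <- function(x, ...) {
  cat(sprintf("Input suite: %d unit-Gaussian vectors of dimension %d\n",
              x$n_inputs, x$dim))
  invisible(x)
}

#' Serialize a network or input suite to JSON
#'
#' The JSON container records layer sizes, activation, the flattened weight
#' vector (layer-major, row-major) and the generating seed, so fixtures can
#' be reused across tests and sessions.
#'
#' @param x a `layered_network` or `input_suite`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly, if written to a file).
#' @export
to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "layered_network")) {
    list(type = "layered_network",
         layer_sizes = x$layer_sizes,
         activation = x$activation,
         weights = flatten_weights(x),
         seed = x$seed)
  } else if (inherits(x, "input_suite")) {
    list(type = "input_suite",
         n_inputs = x$n_inputs,
         dim = x$dim,
         inputs = as.vector(x$inputs),
         seed = x$seed)
  } else {
    stop("to_json() supports layered_network and input_suite objects")
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a network or input suite from JSON
#'
#' @param json a JSON string or file path produced by [to_json()].
#' @return the reconstructed object.
#' @export
from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (identical(obj$type, "layered_network")) {
    net <- make_layered_network(obj$layer_sizes, obj$activation, seed = obj$seed)
    set_weights(net, obj$weights)
  } else if (identical(obj$type, "input_suite")) {
    suite <- make_input_suite(obj$n_inputs, obj$dim, seed = obj$seed)
    suite$inputs <- matrix(obj$inputs, obj$dim, obj$n_inputs)
    suite
  } else {
    stop("unrecognised JSON container type")
  }
}
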