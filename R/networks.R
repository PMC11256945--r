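# Per-view feed-forward networks. Representations are produced by
# H = s(W_M s(... s(W_1 X' + b_1) ...) + b_M)', with the activation applied
# on the final layer as well. Everything is plain dense linear algebra; the
# gradient path lives in training.R.

ACTIVATIONS <- list(
  `leaky-relu` = list(
    f = function(z) z * (0.01 + 0.99 * (z > 0)),
    grad = function(z) 0.01 + 0.99 * (z > 0)
  ),
  tanh = list(
    f = function(z) tanh(z),
    grad = function(z) 1 - tanh(z)^2
  ),
  sigmoid = list(
    f = function(z) 1 / (1 + exp(-z)),
    grad = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }
  ),
  linear = list(
    f = function(z) z,
    grad = function(z) array(1, dim(z))
  )
)

#' Specify a per-view feed-forward network
#'
#' @param input_dim number of input features p_d for this view.
#' @param hidden_dims integer vector of hidden-layer widths (may be empty for
#'   a single affine layer).
#' @param output_dim top-layer width o_d; must stay below the training sample
#'   size so the total covariance of the representations is invertible.
#' @param activation one of \code{"leaky-relu"} (slope 0.01, default),
#'   \code{"tanh"}, \code{"sigmoid"}.
#' @param final_activation apply the activation on the top layer too
#'   (default TRUE, matching the layer recursion); set FALSE for a linear head.
#' @export
network_spec <- function(input_dim, hidden_dims = c(256L, 64L),
                         output_dim = 20L, activation = "leaky-relu",
                         final_activation = TRUE) {
  activation <- match.arg(activation, c("leaky-relu", "tanh", "sigmoid"))
  dims <- c(as.integer(input_dim), as.integer(hidden_dims), as.integer(output_dim))
  if (any(dims < 1)) stop("all layer dimensions must be >= 1")
  structure(list(input_dim = dims[1],
                 hidden_dims = dims[-c(1, length(dims))],
                 output_dim = dims[length(dims)],
                 activation = activation,
                 final_activation = isTRUE(final_activation),
                 dims = dims),
            class = "network_spec")
}

#' Initialize network parameters
#'
#' Seeded He-style initialization: weights N(0, 2/fan_in) for the leaky
#' rectifier, N(0, 1/fan_in) otherwise; zero biases. Deterministic given the
#' seed; the caller's RNG stream is left untouched.
#'
#' @param spec a \code{network_spec}.
#' @param seed integer seed.
#' @export
init_params <- function(spec, seed = 1L) {
  dims <- spec$dims
  gain <- if (spec$activation == "leaky-relu") 2 else 1
  with_local_seed(seed, {
    params <- vector("list", length(dims) - 1)
    for (m in seq_len(length(dims) - 1)) {
      fan_in <- dims[m]
      params[[m]] <- list(
        W = matrix(stats::rnorm(dims[m + 1] * fan_in, sd = sqrt(gain / fan_in)),
                   dims[m + 1], fan_in),
        b = numeric(dims[m + 1]))
    }
    structure(list(layers = params, spec = spec), class = "model_params")
  })
}

#' Forward pass through a view's network
#'
#' @param params \code{model_params} from \code{\link{init_params}} (or as
#'   updated by training).
#' @param X n x p_d input matrix (rows are samples).
#' @param cache if TRUE, also return per-layer pre-activations and outputs
#'   for backpropagation.
#' @return n x o_d representation matrix, or a list with \code{H},
#'   \code{pre} and \code{act} when \code{cache = TRUE}.
#' @export
nn_forward <- function(params, X, cache = FALSE) {
  spec <- params$spec
  X <- as.matrix(X)
  if (ncol(X) != spec$input_dim) {
    stop(sprintf("input has %d columns, expected %d", ncol(X), spec$input_dim))
  }
  act <- ACTIVATIONS[[spec$activation]]
  nlayers <- length(params$layers)
  H <- X
  pre <- vector("list", nlayers)
  outs <- vector("list", nlayers)
  for (m in seq_len(nlayers)) {
    Z <- H %*% t(params$layers[[m]]$W)
    Z <- sweep(Z, 2, params$layers[[m]]$b, `+`)
    linear_head <- (m == nlayers) && !spec$final_activation
    H <- if (linear_head) Z else act$f(Z)
    if (cache) { pre[[m]] <- Z; outs[[m]] <- H }
  }
  if (cache) list(H = H, pre = pre, act = outs) else H
}

# Backpropagate dL/dH through the network; returns gradients for each layer
# and optionally dL/dX. `fwd` is the cached forward pass on X.
nn_backward <- function(params, X, fwd, dH, input_grad = FALSE) {
  spec <- params$spec
  act <- ACTIVATIONS[[spec$activation]]
  nlayers <- length(params$layers)
  grads <- vector("list", nlayers)
  delta <- dH
  for (m in rev(seq_len(nlayers))) {
    linear_head <- (m == nlayers) && !spec$final_activation
    dZ <- if (linear_head) delta else delta * act$grad(fwd$pre[[m]])
    input_m <- if (m == 1) X else fwd$act[[m - 1]]
    grads[[m]] <- list(W = crossprod(dZ, input_m), b = colSums(dZ))
    if (m > 1 || input_grad) delta <- dZ %*% params$layers[[m]]$W
  }
  list(layers = grads, dX = if (input_grad) delta else NULL)
}

# --- model serialization (JSON with numeric arrays; version-tagged) -------

#' Save / load a fitted model
#'
#' Models are stored as a versioned JSON document holding every view's layer
#' sizes, activation, weights and biases, the fitted projection matrices and
#' the preprocessing statistics, so a saved model reproduces predictions
#' exactly.
#'
#' @param model a \code{deep_ida_model}.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  ser_net <- function(params) {
    list(spec = params$spec[c("input_dim", "hidden_dims", "output_dim",
                              "activation", "final_activation")],
         layers = lapply(params$layers, function(l)
           list(W = l$W, b = l$b)))
  }
  doc <- list(
    format = "deepIDA-model", version = 1L,
    networks = lapply(model$params, ser_net),
    Gammas = model$gamma$Gammas,
    eigenvalues = model$gamma$eigenvalues,
    class_levels = model$class_levels,
    standardize = model$standardize,
    centers = model$centers, scales = model$scales,
    config = model$config[c("rho", "l", "epochs", "learning_rate", "ridge",
                            "seed")])
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "deepIDA-model")) stop("not a deepIDA model file")
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r)
    as.numeric(unlist(r))))
  nets <- lapply(doc$networks, function(nd) {
    spec <- network_spec(nd$spec$input_dim,
                         as.integer(unlist(nd$spec$hidden_dims)),
                         nd$spec$output_dim, nd$spec$activation,
                         nd$spec$final_activation)
    layers <- lapply(nd$layers, function(l)
      list(W = as_mat(l$W), b = as.numeric(unlist(l$b))))
    structure(list(layers = layers, spec = spec), class = "model_params")
  })
  model <- list(params = nets,
                gamma = list(Gammas = lapply(doc$Gammas, as_mat),
                             eigenvalues = lapply(doc$eigenvalues,
                                                  function(v) as.numeric(unlist(v)))),
                class_levels = as.character(unlist(doc$class_levels)),
                standardize = isTRUE(doc$standardize),
                centers = lapply(doc$centers, function(v) as.numeric(unlist(v))),
                scales = lapply(doc$scales, function(v) as.numeric(unlist(v))),
                config = doc$config)
  class(model) <- "deep_ida_model"
  model
}
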