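#' Training configuration for the multilayer perceptron
#'
#' Defaults follow the common setup for this kind of one-hot imputation
#' network: batch size 256, 1000 epochs, momentum coefficient 0.9 and three
#' hidden layers of 32 rectifier units.
#'
#' The momentum update here is the damped recurrence
#' \code{v <- beta * v + (1 - beta) * grad}, whose steady-state step is
#' \code{(1 - beta)} times that of the undamped convention
#' (\code{v <- beta * v + grad}) used by most deep-learning libraries. The
#' default \code{learning_rate = 0.01} therefore matches the conventional
#' library setting of 0.001 at \code{beta = 0.9}: the two parameterizations
#' take the same effective optimization step.
#'
#' @param learning_rate Step size alpha (> 0). Default 0.01 (see Details).
#' @param momentum Momentum coefficient beta in [0, 1); \code{0} gives plain
#'   mini-batch gradient descent.
#' @param batch_size Mini-batch size (>= 1); when the data has fewer rows the
#'   full batch is used.
#' @param epochs Number of passes over the data (>= 0).
#' @param hidden Integer vector of hidden-layer widths.
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @return A \code{train_config}.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         batch_size = 256L, epochs = 1000L,
                         hidden = c(32L, 32L, 32L), seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            batch_size >= 1, epochs >= 0, all(hidden >= 1))
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), hidden = as.integer(hidden),
                 seed = seed),
            class = "train_config")
}

#' Initialize a multilayer perceptron
#'
#' Weights are drawn Glorot-uniform on ±sqrt(6 / (fan_in + fan_out)); biases
#' start at zero. Deterministic given the seed.
#'
#' @param layer_dims Integer vector \code{c(input, hidden..., output)}, all
#'   >= 1.
#' @param seed RNG seed.
#' @return An \code{mlp_model} with weight matrices \code{W[[l]]} of shape
#'   (dim_{l-1} x dim_l) and bias vectors \code{b[[l]]}. Hidden layers use the
#'   rectifier, the output layer the logistic sigmoid.
#' @export
init_model <- function(layer_dims, seed = 1L) {
  layer_dims <- as.integer(layer_dims)
  if (length(layer_dims) < 2L || any(layer_dims < 1L)) {
    stop("layer_dims needs >= 2 entries, all >= 1")
  }
  L <- length(layer_dims) - 1L
  model <- list(dims = layer_dims, W = vector("list", L), b = vector("list", L))
  with_seed(seed, {
    for (l in seq_len(L)) {
      fan_in <- layer_dims[l]; fan_out <- layer_dims[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      model$W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                             fan_in, fan_out)
      model$b[[l]] <- rep(0, fan_out)
    }
  })
  class(model) <- "mlp_model"
  model
}

sigmoid <- function(z) 1 / (1 + exp(-z))
relu <- function(z) pmax(z, 0)

#' Forward pass
#'
#' Hidden layers compute \code{relu(X W + b)}, the output layer
#' \code{sigmoid(X W + b)}, so final outputs lie in (0, 1). All intermediate
#' activations are returned for backpropagation.
#'
#' @param model An \code{mlp_model}.
#' @param X Input matrix with \code{model$dims[1]} columns.
#' @return List with \code{activations} (A[[1]] = X, ..., A[[L+1]] = output)
#'   and \code{output}.
#' @export
forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$dims[1]) {
    stop(sprintf("input width %d does not match model input dimension %d",
                 ncol(X), model$dims[1]))
  }
  L <- length(model$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% model$W[[l]] + matrix(model$b[[l]], nrow(X),
                                          length(model$b[[l]]), byrow = TRUE)
    A[[l + 1L]] <- if (l < L) relu(Z) else sigmoid(Z)
  }
  list(activations = A, output = A[[L + 1L]])
}

#' Binary cross-entropy loss
#'
#' Mean over all units of \code{-(t log p + (1 - t) log(1 - p))}, with
#' predictions clipped to [1e-12, 1 - 1e-12] inside the logarithms. Treats
#' the concatenated one-hot blocks as independent binary targets.
#'
#' @param predictions Matrix of values in (0, 1).
#' @param targets 0/1 matrix of the same shape.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(predictions, targets) {
  if (!all(dim(predictions) == dim(targets))) stop("shape mismatch in bce_loss")
  eps <- 1e-12
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

#' Backpropagation
#'
#' Exact gradients of \code{bce_loss(forward(model, X)$output, Y)} with
#' respect to every weight and bias. With sigmoid outputs the output-layer
#' error simplifies to \code{(p - t) / (n * m)} where n x m is the target
#' shape.
#'
#' @param model An \code{mlp_model}.
#' @param X Input matrix.
#' @param Y 0/1 target matrix.
#' @return List with gradient lists \code{dW} and \code{db}, shape-congruent
#'   with the model parameters, plus the forward \code{loss}.
#' @export
backprop <- function(model, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  fw <- forward(model, X)
  A <- fw$activations
  L <- length(model$W)
  if (!all(dim(fw$output) == dim(Y))) stop("target shape mismatch in backprop")
  n_units <- length(Y)
  dZ <- (fw$output - Y) / n_units
  dW <- vector("list", L); db <- vector("list", L)
  for (l in seq(L, 1L)) {
    dW[[l]] <- crossprod(A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, model$W[[l]])
      dZ <- dA * (A[[l]] > 0)  # rectifier derivative
    }
  }
  list(dW = dW, db = db, loss = bce_loss(fw$output, Y))
}

#' Initialize momentum state
#'
#' Velocity tensors matching the model's parameter shapes, all zero.
#'
#' @param model An \code{mlp_model}.
#' @return A \code{momentum_state}.
#' @export
momentum_state <- function(model) {
  structure(list(vW = lapply(model$W, function(w) w * 0),
                 vb = lapply(model$b, function(b) b * 0)),
            class = "momentum_state")
}

#' One momentum gradient-descent step
#'
#' Updates velocities as \code{v <- beta * v + (1 - beta) * grad} and
#' parameters as \code{theta <- theta - alpha * v}. With \code{beta = 0} this
#' is exactly the plain gradient-descent step.
#'
#' @param model An \code{mlp_model}.
#' @param state A \code{\link{momentum_state}}.
#' @param grads Gradients from \code{\link{backprop}}.
#' @param learning_rate Step size alpha.
#' @param momentum Coefficient beta.
#' @return List with the updated \code{model} and \code{state}.
#' @export
momentum_step <- function(model, state, grads, learning_rate, momentum) {
  for (l in seq_along(model$W)) {
    if (!all(is.finite(grads$dW[[l]])) || !all(is.finite(grads$db[[l]]))) {
      stop(sprintf("non-finite gradient in layer %d: training diverged", l))
    }
    state$vW[[l]] <- momentum * state$vW[[l]] + (1 - momentum) * grads$dW[[l]]
    state$vb[[l]] <- momentum * state$vb[[l]] + (1 - momentum) * grads$db[[l]]
    model$W[[l]] <- model$W[[l]] - learning_rate * state$vW[[l]]
    model$b[[l]] <- model$b[[l]] - learning_rate * state$vb[[l]]
  }
  list(model = model, state = state)
}

#' Train a multilayer perceptron
#'
#' Mini-batch momentum gradient descent for a fixed number of epochs. Batches
#' are formed by a seeded reshuffle each epoch; the last short batch is kept.
#' With \code{epochs = 0} the freshly initialized model is returned.
#' Deterministic given \code{config$seed}.
#'
#' @param X Input matrix.
#' @param Y 0/1 target matrix with \code{nrow(Y) == nrow(X)}.
#' @param config A \code{\link{train_config}}.
#' @param model Optional pre-initialized \code{mlp_model}; by default one is
#'   created with dims \code{c(ncol(X), config$hidden, ncol(Y))}.
#' @return List with the trained \code{model} and the per-epoch mean
#'   \code{loss_trace}.
#' @export
train_mlp <- function(X, Y, config = train_config(), model = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(n >= 1L, nrow(Y) == n)
  if (is.null(model)) {
    model <- init_model(c(ncol(X), config$hidden, ncol(Y)),
                        seed = derive_seed(config$seed, 1L))
  }
  state <- momentum_state(model)
  trace <- numeric(config$epochs)
  if (config$epochs == 0L) return(list(model = model, loss_trace = trace))
  bs <- min(config$batch_size, n)
  with_seed(derive_seed(config$seed, 2L), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + bs - 1L, n)]
        g <- backprop(model, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        if (!is.finite(g$loss)) stop("NaN loss: training diverged")
        upd <- momentum_step(model, state, g, config$learning_rate,
                             config$momentum)
        model <- upd$model; state <- upd$state
        losses[bi] <- g$loss
      }
      trace[epoch] <- mean(losses)
    }
  })
  list(model = model, loss_trace = trace)
}

#' Serialize / restore a model as JSON
#'
#' @param model An \code{mlp_model}.
#' @param path File path.
#' @return \code{save_model} returns \code{path} invisibly;
#'   \code{load_model} the restored \code{mlp_model}.
#' @export
save_model <- function(model, path) {
  obj <- list(dims = model$dims,
              W = lapply(model$W, function(w) as.vector(w)),
              b = model$b,
              hidden_activation = "relu", output_activation = "sigmoid")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(obj$dims)
  L <- length(dims) - 1L
  model <- list(dims = dims,
                W = lapply(seq_len(L), function(l) {
                  matrix(obj$W[[l]], dims[l], dims[l + 1L])
                }),
                b = lapply(seq_len(L), function(l) as.numeric(obj$b[[l]])))
  class(model) <- "mlp_model"
  model
}
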