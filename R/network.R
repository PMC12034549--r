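activation_funs <- list(
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                 # derivative expressed through the activation value
                 df = function(a) a * (1 - a)),
  tanh = list(f = base::tanh,
              df = function(a) 1 - a^2)
)

#' Construct a backpropagation network
#'
#' A plain multilayer perceptron: layer g feeds layer g+1 through a weight
#' matrix `W[[g]]` (entry \[i, j\] connects neuron j of layer g to neuron i
#' of layer g+1) and bias vector `b[[g]]`, followed by the activation
#' `f`. Hidden-layer transfer is `h_j = f(sum_i w1_ji x_i + b1_j)` and the
#' output is `y_l = f(sum_j w2_lj h_j + b2_l)`. With `dropout_rate = 0` this
#' is the FCNN; with a positive rate the same object trains as the
#' dropout-regularized network (DNN) — one code path serves both.
#'
#' @param layer_sizes Integer vector, e.g. `c(9, 16, 1)`: input size, hidden
#'   sizes, output size.
#' @param activation `"sigmoid"` (default) or `"tanh"`, used for hidden and
#'   output layers.
#' @param dropout_rate Probability in \[0, 1) of zeroing each hidden unit
#'   during a training-mode forward pass (inverted dropout: survivors are
#'   scaled by 1/(1-p), so inference applies no mask and no scaling).
#' @param init_scale Weights and biases initialised uniformly on
#'   \[-init_scale, init_scale\].
#' @param seed Optional integer seed for the initialisation draw.
#' @return An object of class `ppd_network`.
#' @export
ppd_network <- function(layer_sizes, activation = "sigmoid",
                        dropout_rate = 0, init_scale = 0.1, seed = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    abort("layer_sizes needs at least input and output sizes, all >= 1",
          class = "ppd_config_error")
  }
  if (!activation %in% names(activation_funs)) {
    abort(paste0("unknown activation '", activation, "'"),
          class = "ppd_config_error")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("dropout_rate must lie in [0, 1)", class = "ppd_config_error")
  }
  init <- function() {
    lapply(seq_len(length(layer_sizes) - 1), function(g) {
      matrix(runif(layer_sizes[g + 1] * layer_sizes[g],
                   -init_scale, init_scale),
             layer_sizes[g + 1], layer_sizes[g])
    })
  }
  init_b <- function() {
    lapply(seq_len(length(layer_sizes) - 1), function(g) {
      runif(layer_sizes[g + 1], -init_scale, init_scale)
    })
  }
  if (is.null(seed)) {
    weights <- init(); biases <- init_b()
  } else {
    weights <- NULL
    withr::with_seed(seed, {
      weights <- init(); biases <- init_b()
    })
  }
  structure(
    list(layer_sizes = layer_sizes, weights = weights, biases = biases,
         activation = activation, dropout_rate = dropout_rate),
    class = "ppd_network"
  )
}

#' @export
print.ppd_network <- function(x, ...) {
  cat("<ppd_network> ", paste(x$layer_sizes, collapse = "-"),
      " activation =", x$activation,
      " dropout_rate =", x$dropout_rate, "\n")
  invisible(x)
}

#' Forward pass
#'
#' Propagates a record (or a matrix of records, rows = records) through the
#' network. In training mode with a positive dropout rate, each hidden unit
#' is zeroed independently with probability p and survivors are scaled by
#' 1/(1-p) (inverted dropout); masks are drawn from the current RNG state.
#' Inference mode applies no mask and no scaling.
#'
#' @param net A [ppd_network()].
#' @param x Numeric vector (one record) or matrix (records in rows) with
#'   `net$layer_sizes[1]` columns.
#' @param mode `"infer"` (default) or `"train"`.
#' @return A list of class `ppd_forward` with `activations` (list: input,
#'   then post-mask activations per layer), `raw` (pre-mask activations,
#'   needed for derivatives) and `masks` (per hidden layer, or `NULL`).
#' @export
nn_forward <- function(net, x, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$layer_sizes[1]) {
    abort(sprintf("input has %d columns but the network expects %d",
                  ncol(x), net$layer_sizes[1]),
          class = "ppd_shape_error")
  }
  act <- activation_funs[[net$activation]]$f
  n_layers <- length(net$weights)
  activations <- vector("list", n_layers + 1)
  raw <- vector("list", n_layers + 1)
  masks <- vector("list", n_layers)
  activations[[1]] <- x
  raw[[1]] <- x
  p <- net$dropout_rate
  for (g in seq_len(n_layers)) {
    z <- activations[[g]] %*% t(net$weights[[g]])
    z <- sweep(z, 2, net$biases[[g]], `+`)
    a <- act(z)
    if (any(!is.finite(a))) {
      abort(paste0("non-finite activation in layer ", g + 1),
            class = "ppd_numeric_error")
    }
    raw[[g + 1]] <- a
    if (mode == "train" && p > 0 && g < n_layers) {
      m <- matrix(rbinom(length(a), 1, 1 - p), nrow(a), ncol(a))
      masks[[g]] <- m
      a <- a * m / (1 - p)
    }
    activations[[g + 1]] <- a
  }
  structure(list(activations = activations, raw = raw, masks = masks,
                 mode = mode),
            class = "ppd_forward")
}

#' Squared-error loss
#'
#' `E = 1/2 * sum_l (y_l - d_l)^2` for one record's predicted output `y`
#' and target `d`; for matrices (records in rows) the mean per-record E.
#'
#' @param predicted Numeric vector or matrix of network outputs.
#' @param actual Target values, same shape.
#' @return A single non-negative number, zero iff the outputs match exactly.
#' @export
nn_loss <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("predicted and actual lengths differ", class = "ppd_shape_error")
  }
  if (is.matrix(predicted)) {
    mean(0.5 * rowSums((predicted - actual)^2))
  } else {
    0.5 * sum((predicted - actual)^2)
  }
}

#' Backpropagation gradients
#'
#' Applies the chain rule to the squared-error loss, reusing the forward
#' record's activations and dropout masks exactly. For a matrix of records
#' the gradients are averaged over the mini-batch. Units zeroed by a dropout
#' mask contribute zero gradient through their incident weights.
#'
#' @param net A [ppd_network()].
#' @param fwd A `ppd_forward` record from [nn_forward()] on the same input.
#' @param d Target outputs (vector or matrix matching the output layer).
#' @return A list with `dW` and `db`, shaped like `net$weights`/`net$biases`.
#' @export
nn_backward <- function(net, fwd, d) {
  if (!inherits(fwd, "ppd_forward")) {
    abort("fwd must come from nn_forward()", class = "ppd_shape_error")
  }
  dact <- activation_funs[[net$activation]]$df
  n_layers <- length(net$weights)
  out <- fwd$activations[[n_layers + 1]]
  if (is.vector(d)) d <- matrix(d, nrow = nrow(out))
  if (!all(dim(d) == dim(out))) {
    abort("target shape does not match the output layer",
          class = "ppd_shape_error")
  }
  B <- nrow(out)
  p <- net$dropout_rate
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  # delta = dE/dz at the output layer; E = 1/2 sum (y - d)^2
  delta <- (out - d) * dact(fwd$raw[[n_layers + 1]])
  for (g in rev(seq_len(n_layers))) {
    dW[[g]] <- t(delta) %*% fwd$activations[[g]] / B
    db[[g]] <- colSums(delta) / B
    if (g > 1) {
      back <- delta %*% net$weights[[g]]
      deriv <- dact(fwd$raw[[g]])
      if (fwd$mode == "train" && p > 0 && !is.null(fwd$masks[[g - 1]])) {
        deriv <- deriv * fwd$masks[[g - 1]] / (1 - p)
      }
      delta <- back * deriv
    }
  }
  list(dW = dW, db = db)
}

#' One stochastic-gradient step
#'
#' `w <- w - eta * dE/dw` for every weight and bias.
#'
#' @param net A [ppd_network()].
#' @param grads Gradients from [nn_backward()].
#' @param eta Learning rate, positive.
#' @return The updated network.
#' @export
sgd_step <- function(net, grads, eta) {
  if (eta <= 0) abort("learning rate must be positive",
                      class = "ppd_config_error")
  for (g in seq_along(net$weights)) {
    net$weights[[g]] <- net$weights[[g]] - eta * grads$dW[[g]]
    net$biases[[g]] <- net$biases[[g]] - eta * grads$db[[g]]
  }
  if (any(!vapply(net$weights, function(w) all(is.finite(w)), logical(1)))) {
    abort("non-finite parameter after update", class = "ppd_numeric_error")
  }
  net
}

# min-max scaling of feature columns to [0, 1]; constant columns map to 0
fit_scaling <- function(X) {
  mins <- apply(X, 2, min)
  rngs <- apply(X, 2, max) - mins
  rngs[rngs == 0] <- 1
  list(min = mins, range = rngs)
}

apply_scaling <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$min), 2, scaling$range, `/`)
}

#' Train a backpropagation network on questionnaire data
#'
#' Mini-batch stochastic gradient descent on the squared-error loss with
#' per-epoch shuffling. Feature codes are min-max scaled to \[0, 1\] by
#' default (scaling parameters learned from the training data and stored in
#' the fit). The per-epoch mean per-record loss is recorded, and the
#' training-set accuracy of the final network is computed with the 0.5
#' threshold. A fixed seed yields a bit-identical fit.
#'
#' @param data A data frame holding the predictor columns and the outcome.
#' @param outcome Name of the 0/1 outcome column.
#' @param hidden Integer vector of hidden-layer sizes (default one layer of
#'   16 units).
#' @param activation Activation name, see [ppd_network()].
#' @param dropout_rate Hidden-unit dropout probability; 0 trains the FCNN,
#'   a positive value the DNN.
#' @param learning_rate Step size eta of the weight update.
#' @param epochs Number of passes over the training data (>= 1).
#' @param batch_size Mini-batch size.
#' @param init_scale Uniform initialisation half-width.
#' @param seed Integer seed covering initialisation, shuffling and dropout.
#' @param scale_features Min-max scale features to \[0, 1\]? (default TRUE)
#' @return An object of class `ppd_fit`: the trained network,
#'   `training_accuracy`, `loss_history` (length `epochs`), the scaling and
#'   the configuration.
#' @examples
#' d <- generate_ppd(ppd_generator_spec(n = 120, seed = 7))
#' fit <- train_network(d, epochs = 20, seed = 1)
#' glance(fit)
#' @export
train_network <- function(data, outcome = "Feeling anxious",
                          hidden = 16L, activation = "sigmoid",
                          dropout_rate = 0, learning_rate = 0.1,
                          epochs = 200L, batch_size = 32L,
                          init_scale = 0.1, seed = 1L,
                          scale_features = TRUE) {
  data <- as_tibble(data)
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column '", outcome, "' not found"),
          class = "ppd_schema_error")
  }
  if (epochs < 1) abort("epochs must be >= 1", class = "ppd_config_error")
  if (batch_size < 1) abort("batch_size must be >= 1",
                            class = "ppd_config_error")
  if (learning_rate <= 0) abort("learning_rate must be positive",
                                class = "ppd_config_error")
  feats <- setdiff(names(data), outcome)
  X <- as.matrix(data[feats])
  storage.mode(X) <- "double"
  dimnames(X) <- NULL          # keep weight matrices free of dimnames
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) {
    abort("outcome must be 0/1", class = "ppd_validation_error")
  }
  if (nrow(X) < 1) abort("empty training set", class = "ppd_validation_error")
  scaling <- if (scale_features) fit_scaling(X) else NULL
  if (!is.null(scaling)) X <- apply_scaling(X, scaling)
  n <- nrow(X)
  loss_history <- numeric(epochs)
  net <- NULL
  withr::with_seed(seed, {
    net <- ppd_network(c(ncol(X), hidden, 1L), activation = activation,
                       dropout_rate = dropout_rate,
                       init_scale = init_scale)
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        xb <- X[idx, , drop = FALSE]
        db <- matrix(y[idx], ncol = 1)
        fwd <- nn_forward(net, xb, mode = "train")
        l <- nn_loss(fwd$activations[[length(fwd$activations)]], db)
        if (!is.finite(l)) {
          abort(paste0("training diverged (non-finite loss) at epoch ", e),
                class = "ppd_numeric_error")
        }
        epoch_loss <- epoch_loss + l * length(idx)
        grads <- nn_backward(net, fwd, db)
        net <- sgd_step(net, grads, learning_rate)
      }
      loss_history[e] <- epoch_loss / n
    }
  })
  fit <- structure(
    list(network = net, scaling = scaling, features = feats,
         outcome = outcome, loss_history = loss_history,
         config = list(hidden = hidden, activation = activation,
                       dropout_rate = dropout_rate,
                       learning_rate = learning_rate, epochs = epochs,
                       batch_size = batch_size, init_scale = init_scale,
                       seed = seed, scale_features = scale_features)),
    class = "ppd_fit"
  )
  fit$training_accuracy <-
    mean(predict(fit, data, type = "class") == y)
  fit
}

#' @export
print.ppd_fit <- function(x, ...) {
  cat("<ppd_fit> ", paste(x$network$layer_sizes, collapse = "-"),
      " dropout =", x$network$dropout_rate,
      sprintf(" training accuracy = %.3f\n", x$training_accuracy))
  invisible(x)
}

#' Predict from a trained network
#'
#' @param object A `ppd_fit` from [train_network()].
#' @param newdata Data frame with the fit's predictor columns.
#' @param type `"prob"` for the sigmoid output probability, `"class"` for
#'   0/1 labels (label 1 iff probability >= `threshold`; the tie at the
#'   threshold predicts positive, favouring recall in a screening context).
#' @param threshold Decision threshold, default 0.5.
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer 0/1 labels.
#' @export
predict.ppd_fit <- function(object, newdata, type = c("prob", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata lacks predictor column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ppd_schema_error")
  }
  X <- as.matrix(as_tibble(newdata)[object$features])
  storage.mode(X) <- "double"
  if (!is.null(object$scaling)) X <- apply_scaling(X, object$scaling)
  fwd <- nn_forward(object$network, X, mode = "infer")
  proba <- as.vector(fwd$activations[[length(fwd$activations)]])
  if (type == "prob") proba else as.integer(proba >= threshold)
}

#' @rdname tidy_ppdens
#' @method tidy ppd_fit
#' @export
tidy.ppd_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy_ppdens
#' @method glance ppd_fit
#' @export
glance.ppd_fit <- function(x, ...) {
  tibble(training_accuracy = x$training_accuracy,
         epochs = length(x$loss_history),
         final_loss = x$loss_history[length(x$loss_history)],
         dropout_rate = x$network$dropout_rate)
}

#' Serialize or load a network
#'
#' Stores layer sizes, activation name, dropout rate, row-major weights and
#' biases as JSON at full double precision; the round trip is bit-exact.
#' `write_fit()`/`read_fit()` additionally carry the feature scaling and
#' training metadata so a fit can be reused for prediction.
#'
#' @param net A [ppd_network()].
#' @param path JSON file path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_network <- function(net, path) {
  obj <- list(layer_sizes = net$layer_sizes,
              activation = net$activation,
              dropout_rate = net$dropout_rate,
              weights = lapply(net$weights, function(w) {
                list(nrow = nrow(w), values = as.vector(t(w)))
              }),
              biases = net$biases)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path)
  sizes <- as.integer(unlist(obj$layer_sizes))
  weights <- lapply(obj$weights, function(w) {
    matrix(as.numeric(unlist(w$values)), nrow = as.integer(w$nrow),
           byrow = TRUE)
  })
  biases <- lapply(obj$biases, function(b) as.numeric(unlist(b)))
  structure(list(layer_sizes = sizes, weights = weights, biases = biases,
                 activation = obj$activation,
                 dropout_rate = as.numeric(obj$dropout_rate)),
            class = "ppd_network")
}
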