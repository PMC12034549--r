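#' Ensemble weights from training accuracies and dropout rates
#'
#' The core weighting rule of the model: each member's weight is the average
#' of its share of the summed training accuracies and its share of the
#' summed dropout rates,
#' `w1 = (a1/(a1+a2) + d1/(d1+d2)) / 2` and
#' `w2 = (a2/(a1+a2) + d2/(d1+d2)) / 2`,
#' so `w1 + w2 = 1` identically and the member with higher training accuracy
#' (or larger dropout rate) receives the larger weight. When both dropout
#' rates are zero the dropout shares are defined symmetrically as 1/2 each.
#' Note the formula's asymmetry: with `dropout1 = 0` (the usual FCNN) and
#' comparable accuracies, the dropout share forces `w2 > w1`.
#'
#' All arguments are vectorised.
#'
#' @param accuracy1,accuracy2 Training-set accuracies in \[0, 1\], not both
#'   zero.
#' @param dropout1,dropout2 Dropout rates in \[0, 1).
#' @return A tibble with the four inputs plus `w1` and `w2`.
#' @examples
#' ensemble_weights(0.898, 0.902, 0, 0.5)
#' @export
ensemble_weights <- function(accuracy1, accuracy2, dropout1, dropout2) {
  n <- max(length(accuracy1), length(accuracy2),
           length(dropout1), length(dropout2))
  a1 <- rep_len(as.numeric(accuracy1), n)
  a2 <- rep_len(as.numeric(accuracy2), n)
  d1 <- rep_len(as.numeric(dropout1), n)
  d2 <- rep_len(as.numeric(dropout2), n)
  if (any(a1 < 0 | a1 > 1 | a2 < 0 | a2 > 1)) {
    abort("accuracies must lie in [0, 1]", class = "ppd_config_error")
  }
  if (any(d1 < 0 | d1 >= 1 | d2 < 0 | d2 >= 1)) {
    abort("dropout rates must lie in [0, 1)", class = "ppd_config_error")
  }
  if (any(a1 + a2 == 0)) {
    abort("accuracy1 + accuracy2 must be positive (untrained members?)",
          class = "ppd_config_error")
  }
  acc_share1 <- a1 / (a1 + a2)
  ds <- d1 + d2
  drop_share1 <- ifelse(ds > 0, d1 / ds, 0.5)
  drop_share2 <- ifelse(ds > 0, d2 / ds, 0.5)
  tibble(accuracy1 = a1, accuracy2 = a2, dropout1 = d1, dropout2 = d2,
         w1 = (acc_share1 + drop_share1) / 2,
         w2 = ((1 - acc_share1) + drop_share2) / 2)
}

#' Fit the FCNN + DNN weighted ensemble
#'
#' Trains two networks of the same architecture on the training data — a
#' fully-connected network without dropout (FCNN) and a dropout-regularized
#' one (DNN) — then combines them with [ensemble_weights()] computed from
#' their final training-set accuracies and configured dropout rates. Both
#' members use the same seed, so with `dnn_dropout = 0` they are identical
#' and the ensemble degenerates to either member.
#'
#' @inheritParams train_network
#' @param dnn_dropout Dropout rate of the DNN member (default 0.5).
#' @param fcnn_dropout Dropout value entered for the FCNN in the weighting
#'   rule (default 0; the FCNN has no dropout mechanism, but the rule
#'   formally requires a value).
#' @param threshold Decision threshold on the ensemble probability.
#' @return An object of class `ppd_ensemble` with members `fcnn` and `dnn`
#'   (both `ppd_fit`) and `weights` (one row of [ensemble_weights()]).
#' @examples
#' d <- generate_ppd(ppd_generator_spec(n = 150, seed = 3))
#' mod <- fit_ppd_ensemble(d, epochs = 15, seed = 1)
#' glance(mod)
#' @export
fit_ppd_ensemble <- function(data, outcome = "Feeling anxious",
                             hidden = 16L, activation = "sigmoid",
                             dnn_dropout = 0.5, fcnn_dropout = 0,
                             learning_rate = 0.1, epochs = 200L,
                             batch_size = 32L, init_scale = 0.1,
                             seed = 1L, scale_features = TRUE,
                             threshold = 0.5) {
  fcnn <- train_network(data, outcome = outcome, hidden = hidden,
                        activation = activation, dropout_rate = 0,
                        learning_rate = learning_rate, epochs = epochs,
                        batch_size = batch_size, init_scale = init_scale,
                        seed = seed, scale_features = scale_features)
  dnn <- train_network(data, outcome = outcome, hidden = hidden,
                       activation = activation, dropout_rate = dnn_dropout,
                       learning_rate = learning_rate, epochs = epochs,
                       batch_size = batch_size, init_scale = init_scale,
                       seed = seed, scale_features = scale_features)
  w <- ensemble_weights(fcnn$training_accuracy, dnn$training_accuracy,
                        fcnn_dropout, dnn_dropout)
  structure(list(fcnn = fcnn, dnn = dnn, weights = w,
                 threshold = threshold),
            class = "ppd_ensemble")
}

#' @export
print.ppd_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ppd_ensemble> w1 = %.4f (FCNN, acc %.3f), w2 = %.4f (DNN, acc %.3f, dropout %.2f)\n",
    x$weights$w1, x$weights$accuracy1, x$weights$w2, x$weights$accuracy2,
    x$weights$dropout2))
  invisible(x)
}

#' Predict from a fitted ensemble
#'
#' The ensemble probability is the weighted average
#' `w1 * p_fcnn + w2 * p_dnn` of the members' output probabilities, so it
#' always lies between the two component probabilities; labels threshold
#' the averaged probability (tie predicts positive).
#'
#' @param object A `ppd_ensemble` from [fit_ppd_ensemble()].
#' @param newdata Data frame with the predictor columns.
#' @param type `"prob"`, `"class"`, or `"both"` (a tibble with member and
#'   ensemble probabilities plus the label).
#' @param ... Unused.
#' @return Vector of probabilities or labels, or a tibble for `"both"`.
#' @export
predict.ppd_ensemble <- function(object, newdata,
                                 type = c("prob", "class", "both"), ...) {
  type <- match.arg(type)
  p1 <- predict(object$fcnn, newdata, type = "prob")
  p2 <- predict(object$dnn, newdata, type = "prob")
  proba <- object$weights$w1 * p1 + object$weights$w2 * p2
  label <- as.integer(proba >= object$threshold)
  switch(type,
         prob = proba,
         class = label,
         both = tibble(p_fcnn = p1, p_dnn = p2, p_ensemble = proba,
                       label = label))
}

#' Tidiers for ppdens fits
#'
#' `tidy()` on a `ppd_fit` returns the per-epoch loss history; on a
#' `ppd_ensemble`, one row per member with its accuracy, dropout rate and
#' ensemble weight. `glance()` returns a one-row model summary.
#'
#' @param x A `ppd_fit` or `ppd_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_ppdens
NULL

#' @rdname tidy_ppdens
#' @method tidy ppd_ensemble
#' @export
tidy.ppd_ensemble <- function(x, ...) {
  tibble(member = c("fcnn", "dnn"),
         training_accuracy = c(x$weights$accuracy1, x$weights$accuracy2),
         dropout = c(x$weights$dropout1, x$weights$dropout2),
         weight = c(x$weights$w1, x$weights$w2))
}

#' @rdname tidy_ppdens
#' @method glance ppd_ensemble
#' @export
glance.ppd_ensemble <- function(x, ...) {
  dplyr::bind_cols(x$weights, tibble(threshold = x$threshold))
}

#' Serialize or load a fitted network or ensemble
#'
#' A `ppd_fit` is stored as its network plus the feature scaling and
#' configuration; a `ppd_ensemble` as its two serialized fits plus the
#' weight quadruple and threshold. Round trips are bit-exact.
#'
#' @param fit A `ppd_fit`.
#' @param model A `ppd_ensemble`.
#' @param path JSON file path.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

fit_to_list <- function(fit) {
  list(network = list(layer_sizes = fit$network$layer_sizes,
                      activation = fit$network$activation,
                      dropout_rate = fit$network$dropout_rate,
                      weights = lapply(fit$network$weights, function(w) {
                        list(nrow = nrow(w), values = as.vector(t(w)))
                      }),
                      biases = fit$network$biases),
       scaling = fit$scaling, features = fit$features,
       outcome = fit$outcome, loss_history = fit$loss_history,
       training_accuracy = fit$training_accuracy, config = fit$config)
}

fit_from_list <- function(obj) {
  net <- structure(
    list(layer_sizes = as.integer(unlist(obj$network$layer_sizes)),
         weights = lapply(obj$network$weights, function(w) {
           matrix(as.numeric(unlist(w$values)),
                  nrow = as.integer(w$nrow), byrow = TRUE)
         }),
         biases = lapply(obj$network$biases, function(b) {
           as.numeric(unlist(b))
         }),
         activation = obj$network$activation,
         dropout_rate = as.numeric(obj$network$dropout_rate)),
    class = "ppd_network")
  scaling <- if (is.null(obj$scaling)) NULL else {
    list(min = as.numeric(unlist(obj$scaling$min)),
         range = as.numeric(unlist(obj$scaling$range)))
  }
  structure(
    list(network = net, scaling = scaling,
         features = as.character(unlist(obj$features)),
         outcome = obj$outcome,
         loss_history = as.numeric(unlist(obj$loss_history)),
         training_accuracy = as.numeric(obj$training_accuracy),
         config = obj$config),
    class = "ppd_fit")
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  fit_from_list(jsonlite::read_json(path))
}

#' @rdname write_fit
#' @export
write_ensemble <- function(model, path) {
  obj <- list(fcnn = fit_to_list(model$fcnn),
              dnn = fit_to_list(model$dnn),
              weights = as.list(model$weights),
              threshold = model$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_fit
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(
    list(fcnn = fit_from_list(obj$fcnn),
         dnn = fit_from_list(obj$dnn),
         weights = as_tibble(lapply(obj$weights, as.numeric)),
         threshold = as.numeric(obj$threshold)),
    class = "ppd_ensemble")
}
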