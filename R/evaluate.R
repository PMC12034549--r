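#' Model specification for experiments
#'
#' Bundles the architecture and training hyper-parameters used by the
#' experiment drivers. `model` selects what is trained: the weighted
#' ensemble, or a single FCNN / DNN member.
#'
#' @param model `"ensemble"`, `"fcnn"` or `"dnn"`.
#' @inheritParams fit_ppd_ensemble
#' @return An object of class `ppd_model_spec`.
#' @export
ppd_model_spec <- function(model = c("ensemble", "fcnn", "dnn"),
                           hidden = 16L, activation = "sigmoid",
                           dnn_dropout = 0.5, learning_rate = 0.1,
                           epochs = 200L, batch_size = 32L,
                           init_scale = 0.1, threshold = 0.5,
                           outcome = "Feeling anxious") {
  model <- match.arg(model)
  structure(
    list(model = model, hidden = hidden, activation = activation,
         dnn_dropout = dnn_dropout, learning_rate = learning_rate,
         epochs = epochs, batch_size = batch_size, init_scale = init_scale,
         threshold = threshold, outcome = outcome),
    class = "ppd_model_spec"
  )
}

# train the spec'd model on a training set; returns an object with a
# predict(type = "class") method
fit_model_spec <- function(spec, train, seed) {
  if (spec$model == "ensemble") {
    fit_ppd_ensemble(train, outcome = spec$outcome, hidden = spec$hidden,
                     activation = spec$activation,
                     dnn_dropout = spec$dnn_dropout,
                     learning_rate = spec$learning_rate,
                     epochs = spec$epochs, batch_size = spec$batch_size,
                     init_scale = spec$init_scale, seed = seed,
                     threshold = spec$threshold)
  } else {
    train_network(train, outcome = spec$outcome, hidden = spec$hidden,
                  activation = spec$activation,
                  dropout_rate = if (spec$model == "dnn") spec$dnn_dropout
                                 else 0,
                  learning_rate = spec$learning_rate, epochs = spec$epochs,
                  batch_size = spec$batch_size,
                  init_scale = spec$init_scale, seed = seed)
  }
}

#' Run one split-train-test experiment
#'
#' Splits the data (stratified), trains the specified model on the training
#' side, predicts on the held-out side and reports the nine metrics.
#' Deterministic for a fixed seed.
#'
#' @inheritParams split_ppd
#' @param spec A [ppd_model_spec()].
#' @return A one-row tibble: `model`, `train_fraction`, `seed`, the nine
#'   metrics, `n` (test size) and `flagged`.
#' @export
run_experiment <- function(data, spec = ppd_model_spec(),
                           train_fraction = 0.7, seed = 1L,
                           stratified = TRUE) {
  parts <- split_ppd(data, train_fraction = train_fraction, seed = seed,
                     stratified = stratified)
  fit <- fit_model_spec(spec, parts$train, seed = seed)
  pred <- predict(fit, parts$test, type = "class")
  rep <- metric_report(parts$test[[spec$outcome]], pred)
  dplyr::bind_cols(tibble(model = spec$model,
                          train_fraction = train_fraction,
                          seed = as.integer(seed)), rep)
}

#' Split-ratio sweep
#'
#' Runs [run_experiment()] for every model in `models` at every training
#' fraction in `ratios` (defaults: the 9:1, 8:2, 7:3 and 6:4 ratios), all on
#' seed-derived splits.
#'
#' @inheritParams run_experiment
#' @param models Character vector of model names to sweep.
#' @param ratios Training fractions.
#' @return A tibble with one row per model x ratio.
#' @export
split_sweep <- function(data, models = c("fcnn", "dnn", "ensemble"),
                        ratios = c(0.9, 0.8, 0.7, 0.6), seed = 1L,
                        spec = ppd_model_spec()) {
  purrr::map_dfr(ratios, function(r) {
    purrr::map_dfr(models, function(m) {
      s <- spec
      s$model <- m
      run_experiment(data, s, train_fraction = r, seed = seed)
    })
  })
}

#' Repeated-run accuracy summary
#'
#' Runs the model `k` times (default 30) with run-indexed derived seeds and
#' summarizes the test-set accuracies by worst, mean, median, best and
#' sample standard deviation. Under the default `"resplit"` protocol each
#' run re-draws both the stratified split and the initialisation; under
#' `"fixed_split"` the split is drawn once from `seed` and only the
#' initialisation varies.
#'
#' @inheritParams run_experiment
#' @param k Number of runs (>= 2).
#' @param protocol `"resplit"` or `"fixed_split"`.
#' @return An object of class `ppd_runs` with the accuracy series and the
#'   summary; `glance()` gives the one-row summary, `tidy()` the per-run
#'   accuracies.
#' @export
repeated_runs <- function(data, spec = ppd_model_spec(), k = 30L,
                          train_fraction = 0.7,
                          protocol = c("resplit", "fixed_split"),
                          seed = 1L) {
  protocol <- match.arg(protocol)
  if (k < 2) abort("k must be >= 2", class = "ppd_config_error")
  fixed_parts <- if (protocol == "fixed_split") {
    split_ppd(data, train_fraction = train_fraction, seed = seed)
  } else NULL
  acc <- vapply(seq_len(k), function(run) {
    run_seed <- derive_seed(seed, 10 + run)
    tryCatch({
      parts <- fixed_parts %||%
        split_ppd(data, train_fraction = train_fraction, seed = run_seed)
      fit <- fit_model_spec(spec, parts$train, seed = run_seed)
      mean(predict(fit, parts$test, type = "class") ==
             parts$test[[spec$outcome]])
    }, error = function(e) {
      abort(paste0("run ", run, " failed: ", conditionMessage(e)),
            class = "ppd_run_error")
    })
  }, numeric(1))
  new_ppd_runs(spec$model, acc, protocol, train_fraction)
}

new_ppd_runs <- function(model, accuracies, protocol, train_fraction) {
  structure(
    list(model = model, accuracies = accuracies, protocol = protocol,
         train_fraction = train_fraction,
         summary = tibble(model = model, k = length(accuracies),
                          worst = min(accuracies), mean = mean(accuracies),
                          median = median(accuracies),
                          best = max(accuracies), std = sd(accuracies))),
    class = "ppd_runs"
  )
}

#' @export
print.ppd_runs <- function(x, ...) {
  cat("<ppd_runs> ", x$model, " (", length(x$accuracies), " runs, ",
      x$protocol, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname tidy_ppdens
#' @method tidy ppd_runs
#' @export
tidy.ppd_runs <- function(x, ...) {
  tibble(model = x$model, run = seq_along(x$accuracies),
         accuracy = x$accuracies)
}

#' @rdname tidy_ppdens
#' @method glance ppd_runs
#' @export
glance.ppd_runs <- function(x, ...) x$summary

#' Mann-Whitney U test between two accuracy series
#'
#' Two-sided rank-sum test with midranks for ties. When the pooled size is
#' at most 12 and there are no ties the p-value is exact (full enumeration
#' of rank assignments); otherwise the normal approximation with tie and
#' continuity corrections is used. The reported `u_statistic` counts pairs
#' won by `a` (so U + U' = n1 * n2).
#'
#' @param a,b Non-empty numeric vectors.
#' @return A one-row tibble: `u_statistic`, `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    abort("both samples must be non-empty", class = "ppd_validation_error")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  p <- wt$p.value
  # fully tied pooled sample: zero rank variance, no evidence either way
  if (!is.finite(p)) p <- 1
  tibble(u_statistic = unname(wt$statistic),
         p_value = min(p, 1),
         method = if (use_exact) "exact" else "normal_approx",
         n1 = length(a), n2 = length(b))
}

#' Ablation experiment
#'
#' Trains the FCNN, the DNN and the weighted ensemble on one shared
#' stratified split with shared seeds (the ensemble's members are exactly
#' the two single-model rows) and reports the nine metrics for each.
#'
#' @inheritParams run_experiment
#' @return A three-row tibble (`model` = fcnn, dnn, ensemble) of metric
#'   reports on the common test set.
#' @export
ablate <- function(data, spec = ppd_model_spec(), train_fraction = 0.7,
                   seed = 1L) {
  parts <- split_ppd(data, train_fraction = train_fraction, seed = seed)
  ens <- fit_ppd_ensemble(parts$train, outcome = spec$outcome,
                          hidden = spec$hidden,
                          activation = spec$activation,
                          dnn_dropout = spec$dnn_dropout,
                          learning_rate = spec$learning_rate,
                          epochs = spec$epochs,
                          batch_size = spec$batch_size,
                          init_scale = spec$init_scale, seed = seed,
                          threshold = spec$threshold)
  truth <- parts$test[[spec$outcome]]
  row <- function(name, pred) {
    dplyr::bind_cols(tibble(model = name), metric_report(truth, pred))
  }
  dplyr::bind_rows(
    row("fcnn", predict(ens$fcnn, parts$test, type = "class",
                        threshold = spec$threshold)),
    row("dnn", predict(ens$dnn, parts$test, type = "class",
                       threshold = spec$threshold)),
    row("ensemble", predict(ens, parts$test, type = "class"))
  )
}

#' Baseline classifier adapters
#'
#' An adapter is a named fit/predict pair satisfying the contract
#' `fit(X, y)` (numeric matrix, 0/1 labels) returning a state object, and
#' `predict(state, X)` returning 0/1 labels. Adapters wrap established
#' implementations where one is installed (logistic regression via
#' [stats::glm()], linear discriminant analysis via `MASS::lda()`); k-NN
#' and categorical naive Bayes are small local implementations, and
#' `adapter_majority()` is a constant-prediction control.
#'
#' @param name Adapter display name.
#' @param fit Function `(X, y) -> state`.
#' @param predict Function `(state, X) -> 0/1 labels`.
#' @return An object of class `ppd_adapter`.
#' @export
ppd_adapter <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "ppd_adapter")
}

#' @rdname ppd_adapter
#' @export
adapter_logistic <- function() {
  ppd_adapter(
    "LR",
    fit = function(X, y) {
      df <- as.data.frame(X)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    predict = function(state, X) {
      as.integer(stats::predict(state, as.data.frame(X),
                                type = "response") >= 0.5)
    }
  )
}

#' @rdname ppd_adapter
#' @export
adapter_lda <- function() {
  if (!requireNamespace("MASS", quietly = TRUE)) {
    abort("the LDA adapter needs the MASS package",
          class = "ppd_config_error")
  }
  ppd_adapter(
    "LDA",
    fit = function(X, y) MASS::lda(X, grouping = factor(y)),
    predict = function(state, X) {
      as.integer(as.character(stats::predict(state, X)$class))
    }
  )
}

#' @rdname ppd_adapter
#' @param k Neighbourhood size of the k-NN adapter.
#' @export
adapter_knn <- function(k = 5L) {
  ppd_adapter(
    paste0("KNN", k),
    fit = function(X, y) list(X = X, y = y, k = k),
    predict = function(state, X) {
      # Euclidean distances to every training record; majority label of the
      # k nearest, ties toward the positive class
      d2 <- outer(rowSums(X^2), rowSums(state$X^2), `+`) -
        2 * X %*% t(state$X)
      apply(d2, 1, function(row) {
        nn <- order(row)[seq_len(min(state$k, length(row)))]
        as.integer(mean(state$y[nn]) >= 0.5)
      })
    }
  )
}

#' @rdname ppd_adapter
#' @export
adapter_naive_bayes <- function() {
  ppd_adapter(
    "NBC",
    fit = function(X, y) {
      # categorical NB with Laplace smoothing over the observed code levels
      levs <- lapply(seq_len(ncol(X)), function(j) sort(unique(X[, j])))
      tabs <- lapply(0:1, function(cls) {
        lapply(seq_len(ncol(X)), function(j) {
          x <- X[y == cls, j]
          counts <- vapply(levs[[j]], function(l) sum(x == l) + 1,
                           numeric(1))
          log(counts / sum(counts))
        })
      })
      list(levs = levs, tabs = tabs,
           prior = log(c(mean(y == 0) + 1e-12, mean(y == 1) + 1e-12)))
    },
    predict = function(state, X) {
      score <- function(cls) {
        s <- rep(state$prior[cls + 1], nrow(X))
        for (j in seq_len(ncol(X))) {
          pos <- match(X[, j], state$levs[[j]])
          lp <- state$tabs[[cls + 1]][[j]][pos]
          lp[is.na(lp)] <- log(1e-6)   # unseen level
          s <- s + lp
        }
        s
      }
      as.integer(score(1) >= score(0))
    }
  )
}

#' @rdname ppd_adapter
#' @export
adapter_majority <- function() {
  ppd_adapter(
    "Majority",
    fit = function(X, y) as.integer(mean(y) >= 0.5),
    predict = function(state, X) rep(state, nrow(X))
  )
}

#' @rdname ppd_adapter
#' @export
default_adapters <- function() {
  ads <- list(adapter_logistic(), adapter_knn(), adapter_naive_bayes(),
              adapter_majority())
  if (requireNamespace("MASS", quietly = TRUE)) {
    ads <- c(ads, list(adapter_lda()))
  }
  ads
}

# one adapter run: split, fit, accuracy on the test side
adapter_accuracy <- function(adapter, data, outcome, train_fraction,
                             run_seed) {
  parts <- split_ppd(data, train_fraction = train_fraction, seed = run_seed)
  feats <- setdiff(names(data), outcome)
  Xtr <- as.matrix(parts$train[feats]); storage.mode(Xtr) <- "double"
  Xte <- as.matrix(parts$test[feats]); storage.mode(Xte) <- "double"
  state <- withr::with_seed(run_seed, adapter$fit(Xtr, parts$train[[outcome]]))
  mean(adapter$predict(state, Xte) == parts$test[[outcome]])
}

#' Repeated-run benchmark against baseline classifiers
#'
#' Runs the proposed model and every adapter `k` times on shared
#' run-indexed splits, summarizes each accuracy series, and performs a
#' two-sided Mann-Whitney U test of the proposed model's accuracies against
#' each baseline's. A failing adapter is reported with `NA` statistics and a
#' warning; the benchmark continues.
#'
#' @inheritParams repeated_runs
#' @param adapters List of [ppd_adapter()] objects.
#' @return A list of class `ppd_benchmark`: `summaries` (one row per
#'   classifier, proposed model first), `comparisons` (one Mann-Whitney row
#'   per baseline) and `runs` (the raw accuracy series).
#' @export
benchmark <- function(data, adapters = default_adapters(),
                      spec = ppd_model_spec(), k = 30L,
                      train_fraction = 0.7, seed = 1L) {
  proposed <- repeated_runs(data, spec, k = k,
                            train_fraction = train_fraction, seed = seed)
  runs <- list(proposed = proposed$accuracies)
  summaries <- proposed$summary
  summaries$model <- "proposed"
  comparisons <- NULL
  for (ad in adapters) {
    acc <- tryCatch(
      vapply(seq_len(k), function(run) {
        adapter_accuracy(ad, data, spec$outcome, train_fraction,
                         derive_seed(seed, 10 + run))
      }, numeric(1)),
      error = function(e) {
        warn(paste0("adapter '", ad$name, "' failed: ",
                    conditionMessage(e)))
        NULL
      })
    if (is.null(acc)) {
      summaries <- dplyr::bind_rows(
        summaries,
        tibble(model = ad$name, k = k, worst = NA_real_, mean = NA_real_,
               median = NA_real_, best = NA_real_, std = NA_real_))
      comparisons <- dplyr::bind_rows(
        comparisons,
        tibble(baseline = ad$name, u_statistic = NA_real_,
               p_value = NA_real_, method = NA_character_,
               n1 = k, n2 = k))
      next
    }
    runs[[ad$name]] <- acc
    summaries <- dplyr::bind_rows(summaries,
                                  new_ppd_runs(ad$name, acc, "resplit",
                                               train_fraction)$summary)
    comparisons <- dplyr::bind_rows(
      comparisons,
      dplyr::bind_cols(tibble(baseline = ad$name),
                       mann_whitney(proposed$accuracies, acc)))
  }
  structure(list(summaries = summaries, comparisons = comparisons,
                 runs = runs),
            class = "ppd_benchmark")
}

#' @export
print.ppd_benchmark <- function(x, ...) {
  cat("<ppd_benchmark>\n")
  print(x$summaries)
  cat("\nMann-Whitney vs proposed:\n")
  print(x$comparisons)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
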