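fast_spec <- function(model = "ensemble") {
  ppd_model_spec(model = model, epochs = 15L, hidden = 8L)
}

test_that("run_experiment is deterministic and accepts all paper ratios", {
  d <- generate_ppd(ppd_generator_spec(n = 250, seed = 21))
  r1 <- run_experiment(d, fast_spec(), train_fraction = 0.7, seed = 3)
  r2 <- run_experiment(d, fast_spec(), train_fraction = 0.7, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$model, "ensemble")
  expect_true(all(c("accuracy", "precision", "recall", "f1", "mcc",
                    "specificity", "npv", "fpr", "fnr") %in% names(r1)))

  for (f in c(0.9, 0.8, 0.7, 0.6)) {
    r <- run_experiment(d, fast_spec("fcnn"), train_fraction = f, seed = 1)
    expect_equal(nrow(r), 1)
    expect_equal(r$n, round(250 * (1 - f)))
  }
  expect_error(run_experiment(d, fast_spec(), train_fraction = 1.0),
               class = "ppd_config_error")
})

test_that("split_sweep covers every model at every ratio", {
  d <- generate_ppd(ppd_generator_spec(n = 200, seed = 22))
  sw <- split_sweep(d, models = c("fcnn", "ensemble"),
                    ratios = c(0.8, 0.6), seed = 1,
                    spec = fast_spec())
  expect_equal(nrow(sw), 4)
  expect_setequal(unique(sw$model), c("fcnn", "ensemble"))
  expect_setequal(unique(sw$train_fraction), c(0.8, 0.6))
  expect_true(all(is.finite(sw$accuracy)))
})

test_that("repeated runs summarize the accuracy series correctly", {
  d <- generate_ppd(ppd_generator_spec(n = 200, seed = 23))
  runs <- repeated_runs(d, fast_spec("fcnn"), k = 4, seed = 9)
  acc <- tidy(runs)$accuracy
  expect_length(acc, 4)
  gl <- glance(runs)
  # summary statistics equal a brute-force recomputation from the series
  expect_equal(gl$worst, min(acc))
  expect_equal(gl$best, max(acc))
  expect_equal(gl$mean, mean(acc))
  expect_equal(gl$median, median(acc))
  expect_equal(gl$std, sd(acc))
  expect_true(gl$worst <= gl$median && gl$median <= gl$best)

  # fixed-split protocol holds the partition constant
  runs2 <- repeated_runs(d, fast_spec("fcnn"), k = 3, seed = 9,
                         protocol = "fixed_split")
  expect_length(runs2$accuracies, 3)
  expect_error(repeated_runs(d, fast_spec(), k = 1),
               class = "ppd_config_error")
})

test_that("run summary statistics match hand arithmetic", {
  rs <- ppdens:::new_ppd_runs("toy", c(0.8, 1.0), "resplit", 0.7)
  expect_equal(rs$summary$mean, 0.9)
  expect_equal(round(rs$summary$std, 4), 0.1414)  # sample SD, k - 1
  const <- ppdens:::new_ppd_runs("toy", rep(0.9, 5), "resplit", 0.7)
  expect_equal(const$summary$std, 0)
  expect_equal(const$summary$worst, const$summary$best)
})

test_that("Mann-Whitney matches exact enumeration and handles ties", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 assignments are as extreme
  expect_equal(r$method, "exact")

  oracle <- enum_mw(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, oracle$u)
  expect_equal(r$p_value, oracle$p)

  # identical samples: ties force the normal approximation, p = 1
  a <- c(0.9, 0.91, 0.92, 0.93)
  same <- mann_whitney(a, a)
  expect_equal(same$u_statistic, length(a)^2 / 2)
  expect_equal(same$p_value, 1)
  expect_equal(same$method, "normal_approx")

  # U + U' = n1 * n2
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(6); y <- rnorm(7)
      u1 <- mann_whitney(x, y)$u_statistic
      u2 <- mann_whitney(y, x)$u_statistic
      expect_equal(u1 + u2, 42)
    }
  })
  expect_error(mann_whitney(numeric(0), 1), class = "ppd_validation_error")
})

test_that("ablation reports three models on one shared split", {
  d <- generate_ppd(ppd_generator_spec(n = 200, seed = 24))
  tab <- ablate(d, fast_spec(), train_fraction = 0.7, seed = 2)
  expect_equal(tab$model, c("fcnn", "dnn", "ensemble"))
  expect_equal(nrow(tab), 3)
  expect_true(all(c("accuracy", "precision", "recall", "f1", "mcc",
                    "specificity", "npv", "fpr", "fnr") %in% names(tab)))
  expect_equal(length(unique(tab$n)), 1)   # same test set

  # degenerate case: no dropout and shared seeds -> identical rows
  spec0 <- fast_spec(); spec0$dnn_dropout <- 0
  tab0 <- ablate(d, spec0, train_fraction = 0.7, seed = 2)
  expect_equal(tab0$accuracy, rep(tab0$accuracy[1], 3))
  expect_equal(tab0$mcc, rep(tab0$mcc[1], 3))
})

test_that("adapters satisfy the fit/predict contract", {
  d <- generate_ppd(ppd_generator_spec(n = 300, seed = 25))
  feats <- setdiff(names(d), "Feeling anxious")
  X <- as.matrix(d[feats]); storage.mode(X) <- "double"
  y <- d[["Feeling anxious"]]
  for (ad in default_adapters()) {
    state <- ad$fit(X, y)
    pred <- ad$predict(state, X)
    expect_length(pred, nrow(X))
    expect_true(all(pred %in% c(0L, 1L)), label = ad$name)
  }
  # the constant adapter's accuracy equals the majority share
  maj <- adapter_majority()
  pred <- maj$predict(maj$fit(X, y), X)
  expect_equal(mean(pred == y), max(mean(y), 1 - mean(y)))
})

test_that("benchmark compares the proposed model against every baseline", {
  d <- generate_ppd(ppd_generator_spec(n = 200, seed = 26))
  ads <- list(adapter_majority(), adapter_logistic())
  bm <- benchmark(d, adapters = ads, spec = fast_spec("fcnn"), k = 3,
                  seed = 4)
  expect_equal(nrow(bm$comparisons), 2)
  expect_equal(bm$comparisons$baseline, c("Majority", "LR"))
  expect_equal(bm$summaries$model[1], "proposed")
  expect_equal(nrow(bm$summaries), 3)

  # a failing adapter is isolated, the run continues
  broken <- ppd_adapter("Broken", fit = function(X, y) stop("boom"),
                        predict = function(s, X) 0)
  expect_warning(
    bm2 <- benchmark(d, adapters = list(broken, adapter_majority()),
                     spec = fast_spec("fcnn"), k = 3, seed = 4),
    "Broken")
  expect_true(is.na(bm2$comparisons$p_value[1]))
  expect_false(is.na(bm2$comparisons$p_value[2]))

  # the proposed model against its own series: p = 1
  self <- mann_whitney(bm$runs$proposed, bm$runs$proposed)
  expect_equal(self$p_value, 1)
})
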