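# Independent oracles and small fixtures used across the suite.

schema_names <- ppd_schema()$attributes$name

# a small valid dataset built directly (no generator involved)
tiny_ppd <- function(n = 12, seed = 1) {
  withr::with_seed(seed, {
    cols <- c(
      list(sample(1:5, n, replace = TRUE)),
      lapply(1:8, function(i) sample(1:3, n, replace = TRUE)),
      list(rep_len(c(1L, 0L), n))
    )
    names(cols) <- schema_names
    tibble::as_tibble(cols)
  })
}

# a linearly separable 9-feature toy set: label decided by feature 2
separable_ppd <- function(n = 20) {
  d <- tiny_ppd(n, seed = 42)
  d[["Feeling sad or Tearful"]] <- rep_len(c(1L, 3L), n)
  d[["Feeling anxious"]] <- rep_len(c(1L, 0L), n)
  d
}

# central-difference gradient of the mean-batch squared-error loss with
# respect to every weight and bias (infer mode; independent of nn_backward)
numeric_gradients <- function(net, x, d, h = 1e-5) {
  loss_at <- function(net) {
    fwd <- nn_forward(net, x, mode = "infer")
    out <- fwd$activations[[length(fwd$activations)]]
    nn_loss(out, if (is.matrix(d)) d else matrix(d, nrow = nrow(out)))
  }
  dW <- lapply(seq_along(net$weights), function(g) {
    grad <- net$weights[[g]] * 0
    for (i in seq_along(grad)) {
      up <- net; up$weights[[g]][i] <- up$weights[[g]][i] + h
      dn <- net; dn$weights[[g]][i] <- dn$weights[[g]][i] - h
      grad[i] <- (loss_at(up) - loss_at(dn)) / (2 * h)
    }
    grad
  })
  db <- lapply(seq_along(net$biases), function(g) {
    grad <- net$biases[[g]] * 0
    for (i in seq_along(grad)) {
      up <- net; up$biases[[g]][i] <- up$biases[[g]][i] + h
      dn <- net; dn$biases[[g]][i] <- dn$biases[[g]][i] - h
      grad[i] <- (loss_at(up) - loss_at(dn)) / (2 * h)
    }
    grad
  })
  list(dW = dW, db = db)
}

# relative disagreement used by the gradient checks
rel_err <- function(a, b) abs(a - b) / pmax(1, abs(a), abs(b))

# exact two-sided Mann-Whitney p-value by full enumeration of the
# choose(n1+n2, n1) assignments of pooled ranks to sample one
enum_mw <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  n1 <- length(a)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(b) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu))
  list(u = u_obs, p = min(p, 1))
}

# recompute the nine metrics directly from label vectors via table()
brute_metrics <- function(tp, fp, fn, tn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  est <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  div <- function(num, den) if (den == 0) 0 else num / den
  prec <- div(sum(truth & est), sum(est))
  rec <- div(sum(truth & est), sum(truth))
  spec <- div(sum(!truth & !est), sum(!truth))
  npv <- div(sum(!truth & !est), sum(!est))
  mccd <- sqrt(as.numeric(tp + fp)) * sqrt(tp + fn) * sqrt(tn + fp) *
    sqrt(tn + fn)
  c(accuracy = mean(truth == est),
    precision = prec, recall = rec,
    f1 = div(2 * prec * rec, prec + rec),
    mcc = if (mccd == 0) 0 else (tp * tn - as.numeric(fp) * fn) / mccd,
    specificity = spec, npv = npv,
    fpr = div(fp, fp + tn), fnr = div(fn, fn + tp))
}
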