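# Brute-force reference implementations used as independent oracles.
# Each is a direct loop over the definition, deliberately naive.

oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

oracle_mse_top1 <- function(observed, imputed, selector) {
  n <- length(observed)
  m <- ceiling(0.01 * n)
  # stable sort by decreasing selector, position order breaking ties
  idx <- seq_len(n)
  ord <- idx[order(-selector, idx)]
  top <- ord[1:m]
  oracle_mse(observed[top], imputed[top])
}

oracle_mse_mask <- function(observed, imputed, mask0) {
  s <- 0
  for (b in mask0) s <- s + (observed[b + 1] - imputed[b + 1])^2
  s / length(mask0)
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

# threshold sweep over distinct scores, descending
oracle_average_precision <- function(scores, labels) {
  P <- sum(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (th in thresholds) {
    pred <- scores >= th
    tp <- sum(labels & pred)
    prec <- tp / sum(pred)
    rec <- tp / P
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

oracle_epr <- function(scores, labels) {
  P <- sum(labels)
  idx <- seq_along(scores)
  ord <- idx[order(-scores, idx)]
  k <- P
  while (k < length(scores) && scores[ord[k + 1]] == scores[ord[P]]) k <- k + 1
  chosen <- ord[1:k]
  sum(labels[chosen]) / k
}

# counter walk over biosamples in given order, experiments in given order
oracle_fold_walk <- function(experiments, k) {
  counter <- 0
  fold <- integer(nrow(experiments))
  for (b in unique(experiments$biosample)) {
    for (i in which(experiments$biosample == b)) {
      fold[i] <- counter %% k + 1
      counter <- counter + 1
    }
  }
  fold
}

oracle_window_means <- function(values, wb, sb) {
  out <- numeric(0)
  s <- 0
  while (s < length(values)) {
    out <- c(out, mean(values[(s + 1):min(s + wb, length(values))]))
    s <- s + sb
  }
  out
}
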