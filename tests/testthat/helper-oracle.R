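# Independent brute-force TOPSIS oracle: naive loops, no shared code with
# the package implementation.

topsis_oracle <- function(values, directions, weights = rep(1, ncol(values)),
                          normalization = "vector") {
  n <- nrow(values)
  m <- ncol(values)
  r <- matrix(0, n, m)
  for (j in seq_len(m)) {
    if (normalization == "vector") {
      ss <- 0
      for (i in seq_len(n)) ss <- ss + values[i, j]^2
      for (i in seq_len(n)) r[i, j] <- values[i, j] / sqrt(ss)
    } else {
      lo <- min(values[, j])
      hi <- max(values[, j])
      for (i in seq_len(n)) {
        r[i, j] <- if (hi == lo) 0.5 else (values[i, j] - lo) / (hi - lo)
      }
    }
  }
  v <- matrix(0, n, m)
  wsum <- sum(weights)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) v[i, j] <- r[i, j] * weights[j] / wsum
  }
  best <- numeric(m)
  worst <- numeric(m)
  for (j in seq_len(m)) {
    if (directions[j] == "gap_increasing") {
      best[j] <- min(v[, j])
      worst[j] <- max(v[, j])
    } else {
      best[j] <- max(v[, j])
      worst[j] <- min(v[, j])
    }
  }
  g <- numeric(n)
  for (i in seq_len(n)) {
    db <- sqrt(sum((v[i, ] - best)^2))
    dw <- sqrt(sum((v[i, ] - worst)^2))
    g[i] <- if (db + dw > 0) db / (db + dw) else 0.5
  }
  g
}

random_decision_values <- function(n, m, scale = 100) {
  matrix(runif(n * m, 0.01, scale), n, m)
}

random_directions <- function(m) {
  sample(c("gap_increasing", "gap_decreasing"), m, replace = TRUE)
}
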