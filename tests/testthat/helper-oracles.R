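# Independent oracles: plain-R transcriptions of the textbook definitions,
# kept free of any package internals so they can arbitrate the C++ filter,
# the rank-based AUC and the queue simulator.

# Holt-Winters recursions, one explicit loop per variant.
hw_oracle <- function(y, m, alpha, beta, gamma, phi = 1,
                      l0, b0, s0, variant) {
  n <- length(y)
  level <- trend <- fitted <- numeric(n)
  s <- c(s0, numeric(n))
  l <- l0; b <- b0
  for (t in seq_len(n)) {
    s_lag <- s[t]
    if (variant == "additive") {
      yh <- l + b + s_lag
      l_new <- alpha * (y[t] - s_lag) + (1 - alpha) * (l + b)
      b_new <- beta * (l_new - l) + (1 - beta) * b
      s_new <- gamma * (y[t] - l - b) + (1 - gamma) * s_lag
    } else if (variant == "damped") {
      yh <- l + phi * b + s_lag
      l_new <- alpha * (y[t] - s_lag) + (1 - alpha) * (l + phi * b)
      b_new <- beta * (l_new - l) + (1 - beta) * phi * b
      s_new <- gamma * (y[t] - l - phi * b) + (1 - gamma) * s_lag
    } else { # multiplicative
      yh <- (l + b) * s_lag
      l_new <- alpha * (y[t] / s_lag) + (1 - alpha) * (l + b)
      b_new <- beta * (l_new - l) + (1 - beta) * b
      s_new <- gamma * (y[t] / (l + b)) + (1 - gamma) * s_lag
    }
    level[t] <- l_new; trend[t] <- b_new; s[m + t] <- s_new; fitted[t] <- yh
    l <- l_new; b <- b_new
  }
  list(level = level, trend = trend, seasonal = s[(m + 1):(m + n)],
       s_final = s[(n + 1):(n + m)], fitted = fitted,
       residuals = y - fitted)
}

# forecasts from a final state, straight from the closed-form equations
hw_oracle_forecast <- function(state, m, h, variant, phi = 1) {
  sapply(seq_len(h), function(k) {
    s <- state$s_final[((k - 1) %% m) + 1]
    if (variant == "additive") state$level[length(state$level)] +
      k * state$trend[length(state$trend)] + s
    else if (variant == "damped") state$level[length(state$level)] +
      sum(phi^seq_len(k)) * state$trend[length(state$trend)] + s
    else (state$level[length(state$level)] +
            k * state$trend[length(state$trend)]) * s
  })
}

# all-pairs AUC with half credit for ties
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# binormal evaluation pairs with a known generating AUC of pnorm(mu/sqrt(2))
binormal_pairs <- function(n_pos, n_neg, mu) {
  tibble::tibble(
    score = c(rnorm(n_pos, mu), rnorm(n_neg)),
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
}

# simulate from the additive Holt-Winters innovations recursion:
# y_t = l + b + s_lag + e;  l += b + alpha e;  b += alpha beta e;
# s_new = s_lag + gamma e   (algebraically identical to applying the
# smoothing updates to the observed y)
sim_additive_hw <- function(n, m, alpha, beta, gamma, sigma, seed,
                            l0 = 50, s_amp = 10) {
  set.seed(seed)
  s <- c(s_amp * sin(2 * pi * (0:(m - 1)) / m), numeric(n))
  s <- s - mean(s[1:m])
  l <- l0; b <- 0
  y <- numeric(n)
  for (t in seq_len(n)) {
    e <- rnorm(1, 0, sigma)
    y[t] <- l + b + s[t] + e
    l_new <- l + b + alpha * e
    b <- b + alpha * beta * e
    s[m + t] <- s[t] + gamma * e
    l <- l_new
  }
  y
}

hourly_ts <- function(values, start = "2022-01-01") {
  tibble::tibble(
    timestamp = as.POSIXct(start, tz = "UTC") + 3600 * (seq_along(values) - 1),
    value = values
  )
}
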