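# Independent brute-force oracles used to cross-check the vectorized
# implementation. Deliberately written as naive loops, sharing no code with
# the package internals.

# Sliding-window chart by explicit double loop.
oracle_chart <- function(v, window_length = 30, overlap = 29,
                         normalizer = "n_windows") {
  L <- length(v)
  stride <- window_length - overlap
  wl <- if (L < window_length) L else window_length
  starts <- if (L < window_length) 1L else seq(1L, L - wl + 1L, by = stride)
  W <- length(starts)
  y <- numeric(W)
  for (k in seq_len(W)) {
    acc <- 0
    for (j in starts[k]:(starts[k] + wl - 1L)) acc <- acc + v[j]
    y[k] <- acc
  }
  div <- switch(normalizer, n_windows = W, window_length = window_length, none = 1)
  data.frame(x = seq_len(W), y = y / div)
}

# Peak/trough counts by scanning maximal sign runs.
oracle_counts <- function(y, eps = 1e-12) {
  peaks <- 0L
  troughs <- 0L
  prev <- 0L
  for (v in y) {
    s <- if (v > eps) 1L else if (v < -eps) -1L else 0L
    if (s == 1L && prev != 1L) peaks <- peaks + 1L
    if (s == -1L && prev != -1L) troughs <- troughs + 1L
    prev <- s
  }
  list(peaks = peaks, troughs = troughs)
}

# High-resolution numerical integration of the piecewise-linear interpolant:
# midpoint rule on a fine subdivision of every span.
oracle_integral <- function(x, y, sub = 200L) {
  total <- 0
  f <- approxfun(x, y)
  for (i in seq_len(length(x) - 1L)) {
    grid <- seq(x[i], x[i + 1L], length.out = sub + 1L)
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    total <- total + sum(f(mids)) * (x[i + 1L] - x[i]) / sub
  }
  total
}

# Random valence series in [-1, 1] with a controllable share of exact zeros.
rand_series <- function(n, zero_frac = 0.4) {
  v <- runif(n, -1, 1)
  v[runif(n) < zero_frac] <- 0
  v
}

# Wrap a valence vector as a scores tibble for dream_charts().
as_scores <- function(v, id = "r1") {
  data.frame(report_id = id, position = seq_along(v), valence = v)
}

# Wrap an (x, y) pair as a chart tibble.
as_chart <- function(y, id = "r1", x = seq_along(y)) {
  data.frame(report_id = id, x = x, y = y)
}
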