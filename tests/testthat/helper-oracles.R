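# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and stats::quantile/var where the convention matters):
# percentiles from sorted order statistics with explicit interpolation,
# moments from explicit loops, ANOVA mean squares from explicit sums.

bf_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

bf_summary <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n
  ss <- m2 <- m3 <- m4 <- 0
  for (v in x) {
    d <- v - m
    ss <- ss + d * d
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  s <- sort(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  list(n = n, mean = m,
       sd = if (n >= 2) sqrt(ss / (n - 1)) else 0,
       median = med,
       p10 = bf_quantile(x, 0.10), p25 = bf_quantile(x, 0.25),
       p75 = bf_quantile(x, 0.75), p90 = bf_quantile(x, 0.90),
       skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
       kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NA_real_)
}

# two-way crossed ANOVA mean squares by explicit summation
bf_two_way_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- ssc <- sse <- 0
  rme <- rowSums(m) / k
  cme <- colSums(m) / n
  for (i in seq_len(n)) ssr <- ssr + k * (rme[i] - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (cme[j] - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (m[i, j] - rme[i] - cme[j] + grand)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), .Machine$double.xmin)

# error on a dimensionless O(1) statistic: relative, but floored at scale 1 so
# catastrophic cancellation in a near-zero third/fourth moment (where both
# implementation and oracle only agree to ~1e-14 absolute) is not amplified
shape_err <- function(x, ref) abs(x - ref) / max(abs(ref), 1)

# cheap longitudinal series with prescribed per-week medians and GTV volumes
make_series <- function(medians, volumes = rep(10, length(medians)),
                        weeks = seq_along(medians) - 1L, id = "g") {
  tps <- mapply(function(w, v, vol) {
    time_point(w, summarize_histogram(v * c(0.999, 1, 1.001)), vol)
  }, weeks, medians, volumes, SIMPLIFY = FALSE)
  longitudinal_series(id, tps)
}

# small fast phantom spec for unit tests
tiny_phantom_spec <- function(..., grid = c(24L, 24L, 10L)) {
  phantom_spec(grid_shape = grid,
               compartments = default_compartments(grid),
               ...)
}
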