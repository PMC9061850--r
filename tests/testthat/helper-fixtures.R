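# Shared fixture builders and independent brute-force oracles.

# noise-free logistic aggregation curve A / (1 + exp(-k (t - t0)))
logistic_curve <- function(A = 1000, k = 1, t0 = 25,
                           t = seq(0, 50, by = 0.05)) {
  list(t = t, y = A / (1 + exp(-k * (t - t0))), A = A, k = k, t0 = t0)
}

# closed-form 5%-threshold crossing times of the logistic first derivative:
# d1 = (A k / 4) sech^2(k (t - t0) / 2) crosses frac of its max where
# sech^2(x) = frac, i.e. t = t0 +/- (2 / k) acosh(sqrt(1 / frac))
logistic_crossings <- function(k, t0, frac = 0.05) {
  x <- acosh(sqrt(1 / frac))
  c(start = t0 - 2 * x / k, end = t0 + 2 * x / k)
}

# brute-force linear-scan segmentation oracle: literal implementation of the
# threshold definitions, index by index
segment_brute <- function(t, d1, frac = 0.05) {
  dmax <- max(d1)
  if (dmax <= 0) return(NULL)
  thr <- frac * dmax
  imax <- which(d1 == dmax)[1]
  start <- NA_integer_
  for (i in seq_along(d1)) if (d1[i] >= thr) { start <- i; break }
  end <- length(d1)
  for (i in seq_along(d1)) {
    if (i > imax && d1[i] <= thr) { end <- i; break }
  }
  list(start = start, end = end, lag_time = t[start])
}

# brute-force shrinking-window moving average
smooth_brute <- function(y, window) {
  half <- (window - 1) %/% 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    mean(y[(i - h):(i + h)])
  }, numeric(1))
}

# random sigmoid-plus-noise curve with a unique derivative maximum
random_sigmoid <- function() {
  A <- runif(1, 100, 2000)
  k <- runif(1, 0.3, 2)
  t0 <- runif(1, 10, 35)
  t <- seq(0, 50, by = 0.25)
  y <- A / (1 + exp(-k * (t - t0))) + rnorm(length(t), 0, A / 200)
  list(t = t, y = y)
}

# tiny 3-residue peak list
peaks3 <- function(dH = 0, dX = 0, I = c(100, 100, 100)) {
  data.frame(residue = 1:3,
             shift_H = c(8.1, 8.3, 8.5) + dH,
             shift_X = c(115, 120, 125) + dX,
             intensity = I)
}
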