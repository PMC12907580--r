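# Shared fixtures built in code.

# A session with constant temperature and heart rate.
const_session <- function(trec = 38, hr = 120, baseline = 36.9,
                          times = seq(0, 120, 5)) {
  list(trec_series = time_series(times, rep(trec, length(times))),
       hr_series = time_series(times, rep(hr, length(times))),
       baseline_trec = baseline, duration = diff(range(times)))
}

# A piecewise-linear session with known samples on the 5-min grid.
ramp_session <- function(trec_start = 37.0, trec_end = 38.5,
                         hr_start = 85, hr_end = 145, baseline = 36.9) {
  times <- seq(0, 120, 5)
  list(trec_series = time_series(times, seq(trec_start, trec_end,
                                            length.out = length(times))),
       hr_series = time_series(times, seq(hr_start, hr_end,
                                          length.out = length(times))),
       baseline_trec = baseline, duration = 120)
}

# Random piecewise-linear series for property checks.
random_series <- function(n = 25, lo = 36.5, hi = 39.5) {
  times <- sort(sample(seq(0, 120, 2.5), n))
  while (length(unique(times)) < n) times <- sort(sample(seq(0, 120, 2.5), n))
  time_series(times, stats::runif(n, lo, hi))
}

# Independent dense-grid trapezoid oracle for areas above a threshold:
# interpolate the piecewise-linear series on a fine grid, clamp, integrate.
# The step is fine enough that the oracle's own discretisation error at
# threshold crossings stays below the 1e-6 relative comparison tolerance.
riemann_auc_above <- function(series, threshold, h = 1e-4) {
  tt <- seq(min(series$times), max(series$times), by = h)
  vv <- stats::approx(series$times, series$values, xout = tt)$y
  y <- pmax(vv - threshold, 0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(tt))
}

# Full hypergeometric enumeration oracle for the two-sided Fisher test
# (probability-mass rule), independent of stats::fisher.test.
enumerate_fisher_p <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Reconstructed per-criterion intolerance percentages as printed, pooled and
# by sex, with their denominators (21 females, 19 males, 40 total).
printed_rates <- function() {
  list(
    pre_all  = c(15.0, 40.0, 37.5, 50.0, 67.5, 75.0, 90.0),
    post_all = c(10.0, 7.5, 5.0, 15.0, 40.0, 32.5, 67.5),
    pre_f  = c(9.5, 42.9, 61.9, 71.4, 90.5, 85.7, 100.0),
    post_f = c(9.5, 9.5, 9.5, 23.8, 61.9, 38.1, 76.2),
    pre_m  = c(21.1, 36.8, 10.5, 26.3, 42.1, 63.2, 78.9),
    post_m = c(10.5, 5.3, 0.0, 5.3, 15.8, 26.3, 57.9),
    n_all = 40L, n_f = 21L, n_m = 19L
  )
}
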