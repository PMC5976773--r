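# Independent reference implementations used to cross-check the package.

# Closed-form amplitude response of the first-order Butterworth band-pass
# that the package is specified to implement: analog prototype
# |H(jW)| = B W / sqrt((w0^2 - W^2)^2 + (B W)^2) evaluated at the bilinear
# warped frequency W(f) = 2 fs tan(pi f / fs), with both cutoffs prewarped.
oracle_bandpass_gain <- function(f, low_hz, high_hz, fs) {
  warp <- function(g) 2 * fs * tan(pi * g / fs)
  w1 <- warp(low_hz); w2 <- warp(high_hz)
  B <- w2 - w1; w0sq <- w1 * w2
  W <- warp(f)
  B * W / sqrt((w0sq - W^2)^2 + (B * W)^2)
}

# Steady-state amplitude of a filtered unit sinusoid, measured empirically by
# least-squares projection onto sin/cos over the second half of the trace.
measure_gain <- function(f, fs = 12500, spec = filter_spec(), dur_s = 1) {
  t <- seq(0, dur_s, by = 1 / fs)
  y <- bandpass_filter(voltage_trace(sin(2 * pi * f * t), fs = fs), spec)$samples
  keep <- seq(floor(length(t) / 2), length(t))
  X <- cbind(sin(2 * pi * f * t[keep]), cos(2 * pi * f * t[keep]))
  sqrt(sum(stats::lm.fit(X, y[keep])$coefficients^2))
}

# Exhaustive per-sample spike scan: same threshold sequence and suppression
# rule as detect_spikes, written as a naive stateful loop.
oracle_detect <- function(x, fs, tspec) {
  thr <- neuroassay::rolling_std(x, tspec$window_s, fs = fs)
  mag <- switch(tspec$polarity, both = abs(x), negative = -x, positive = x)
  exceed <- mag > tspec$k * thr
  events <- numeric(0)
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (exceed[i]) {
      best <- i
      j <- i
      while (j < n && exceed[j + 1L]) {
        j <- j + 1L
        if (mag[j] > mag[best]) best <- j
      }
      events <- c(events, (best - 1L) / fs)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (tspec$dead_time_s > 0 && length(events) > 1L) {
    kept <- events[1]
    for (e in events[-1]) if (e - kept[length(kept)] >= tspec$dead_time_s)
      kept <- c(kept, e)
    events <- kept
  }
  events
}

# Brute-force candidate-peak enumeration: test every index for (plateau)
# local-maximum status, then walk each flank sample by sample under the
# strict-descent rule.
oracle_peaks <- function(y) {
  n <- length(y)
  out <- NULL
  for (i in seq_len(n)) {
    if (i == 1L || i == n || y[i] <= y[i - 1L]) next
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    if (j == n || y[j + 1L] >= y[i]) next
    p <- i + (j - i) %/% 2L
    L <- i
    while (L > 1L && y[L - 1L] < y[L]) L <- L - 1L
    R <- j
    while (R < n && y[R + 1L] < y[R]) R <- R + 1L
    if (L < i && R > j) out <- rbind(out, c(L, p, R))
  }
  if (is.null(out)) {
    out <- matrix(integer(0), ncol = 3)
  }
  dimnames(out) <- list(NULL, c("left_min", "peak", "right_min"))
  out
}

# Match detected event times against ground truth at a tolerance; greedy
# one-to-one assignment in time order.
match_events <- function(detected, truth, tol_s) {
  used <- logical(length(detected))
  tp <- 0L
  for (tt in truth) {
    j <- which(!used & abs(detected - tt) <= tol_s)
    if (length(j)) {
      used[j[which.min(abs(detected[j] - tt))]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = sum(!used), fn = length(truth) - tp)
}

# random short traces for delimitation fuzzing: mixture of smooth bumps,
# integer-valued plateaus and white noise
random_short_trace <- function(n = 50) {
  kind <- sample(3, 1)
  if (kind == 1) round(stats::rnorm(n), sample(0:1, 1))
  else if (kind == 2) sample(0:4, n, replace = TRUE)
  else cumsum(stats::rnorm(n))
}
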