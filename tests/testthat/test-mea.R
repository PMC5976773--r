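test_that("band-pass filter kills DC and is linear", {
  tr <- voltage_trace(rep(5, 5000), fs = 12500)
  y <- bandpass_filter(tr)$samples
  expect_lt(max(abs(y[2000:5000])), 1e-6)

  set.seed(1)
  x <- rnorm(2000)
  f1 <- bandpass_filter(voltage_trace(3.7 * x, fs = 12500))$samples
  f2 <- 3.7 * bandpass_filter(voltage_trace(x, fs = 12500))$samples
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("filter gain at the cutoffs is -3 dB and matches the analytic response", {
  for (f in c(200, 2500)) {
    g <- measure_gain(f)
    expect_equal(20 * log10(g), -20 * log10(2) / 2, tolerance = 0.5)
  }
  # mid-band probe against the closed-form transfer function
  g707 <- measure_gain(707)
  expect_equal(g707, oracle_bandpass_gain(707, 200, 2500, 12500), tolerance = 0.01)
  # and against the package's own response function
  expect_equal(g707, bandpass_gain(707, filter_spec(), fs = 12500), tolerance = 0.01)
})

test_that("filter rejects cutoffs at or above Nyquist, naming the value", {
  tr <- voltage_trace(rnorm(100), fs = 4000)
  expect_error(bandpass_filter(tr, filter_spec(200, 2500)), "2500")
})

test_that("rolling_std edge cases follow the window contract", {
  expect_equal(rolling_std(rep(2, 100), window_s = 0.01, fs = 1000), rep(0, 100))
  # window equal to the full trace: every value is the global SD
  set.seed(2)
  x <- rnorm(200)
  expect_equal(rolling_std(x, window_s = 200, fs = 1), rep(sd(x), 200))
  # longer than the trace: global SD with a message
  expect_message(r <- rolling_std(x, window_s = 500, fs = 1), "global SD")
  expect_equal(r, rep(sd(x), 200))
  expect_error(rolling_std(x, window_s = 0.001, fs = 1000), "at least 2")
})

test_that("rolling_std recovers a known noise level", {
  set.seed(3)
  sigma <- 3
  tr <- voltage_trace(rnorm(25000, 0, sigma), fs = 12500)
  rs <- rolling_std(tr, window_s = 0.1)
  expect_equal(length(rs), 25000)
  expect_lt(abs(median(rs) - sigma) / sigma, 0.05)
  expect_true(all(rs > 0))
  # matches a literal per-sample sd() loop on a short trace
  x <- rnorm(50)
  rs2 <- rolling_std(x, window_s = 11, fs = 1)
  ref <- sapply(seq_along(x), function(i) {
    h <- max(1, min(5, i - 1, length(x) - i))
    sd(x[max(1, i - h):min(length(x), i + h)])
  })
  expect_equal(rs2, ref, tolerance = 1e-12)
})

test_that("detect_spikes returns empty trains on silent input and warns when unfiltered", {
  tr <- voltage_trace(rep(0, 3000), fs = 12500, filtered = TRUE)
  st <- detect_spikes(tr)
  expect_s3_class(st, "spike_train")
  expect_length(st$timestamps, 0)
  expect_warning(detect_spikes(voltage_trace(rnorm(3000), fs = 12500)), "filtered")
})

test_that("detect_spikes equals the exhaustive per-sample oracle", {
  tspec <- threshold_spec(k = 3, window_s = 0.02, dead_time_s = 0.002)
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(5000)
    # salt with a few large deflections so events exist
    idx <- sample(100:4900, 5)
    x[idx] <- x[idx] + sample(c(-8, 8), 5, replace = TRUE)
    tr <- voltage_trace(x, fs = 12500, filtered = TRUE)
    expect_equal(detect_spikes(tr, tspec)$timestamps,
                 oracle_detect(x, 12500, tspec))
  }
})

test_that("spike count is monotone non-increasing in k and respects dead time", {
  set.seed(4)
  x <- rnorm(20000)
  x[seq(500, 19500, by = 700)] <- 10
  tr <- voltage_trace(x, fs = 12500, filtered = TRUE)
  counts <- sapply(c(2, 3, 4, 5.25, 7), function(k)
    length(detect_spikes(tr, threshold_spec(k = k))$timestamps))
  expect_true(all(diff(counts) <= 0))
  for (dt in c(0.001, 0.01, 0.05)) {
    ts <- detect_spikes(tr, threshold_spec(k = 3, dead_time_s = dt))$timestamps
    if (length(ts) > 1) expect_true(all(diff(ts) >= dt))
  }
})

test_that("polarity settings select the expected excursions", {
  x <- rep(0.001, 6000)
  set.seed(5)
  x <- x + rnorm(6000, 0, 1)
  x[1000] <- -12; x[3000] <- 12
  tr <- voltage_trace(x, fs = 12500, filtered = TRUE)
  t_neg <- detect_spikes(tr, threshold_spec(k = 6, polarity = "negative"))$timestamps
  t_pos <- detect_spikes(tr, threshold_spec(k = 6, polarity = "positive"))$timestamps
  t_both <- detect_spikes(tr, threshold_spec(k = 6, polarity = "both"))$timestamps
  expect_equal(t_neg, 999 / 12500)
  expect_equal(t_pos, 2999 / 12500)
  expect_equal(t_both, c(999, 2999) / 12500)
})

test_that("well_spike_rate aggregates per the documented rule", {
  empty <- lapply(sprintf("e%02d", 0:63), function(e)
    spike_train(numeric(0), electrode_id = e, well_id = "w", duration_s = 600))
  ws <- well_spike_rate(empty, duration_s = 600)
  expect_equal(ws$well_mean_rate, 0)
  expect_equal(ws$n_active, 0)
  expect_equal(ws$well_mean_rate_active, 0)

  one <- empty
  one[[1]] <- spike_train(seq(0.5, 599.5, length.out = 600), electrode_id = "e00",
                          well_id = "w", duration_s = 600)
  ws1 <- well_spike_rate(one, duration_s = 600)
  expect_equal(unname(ws1$electrode_rates["e00"]), 1)
  expect_equal(ws1$well_mean_rate, 1 / 64)
  expect_equal(ws1$n_active, 1)
  expect_equal(ws1$well_mean_rate_active, 1)
  expect_error(well_spike_rate(one, duration_s = 0), "positive")
})

test_that("raster export round-trips and is sorted electrode-major", {
  t1 <- spike_train(c(0.25, 0.5), electrode_id = "e01", well_id = "w1", duration_s = 1)
  t2 <- spike_train(0.1, electrode_id = "e00", well_id = "w1", duration_s = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- export_raster(list(t1, t2), path)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$electrode, c("e00", "e01", "e01"))
  expect_equal(tab$timestamp_s, c(0.1, 0.25, 0.5))
  back <- read_raster(path, duration_s = 1)
  expect_equal(back[[1]]$timestamps, 0.1)
  expect_equal(back[[2]]$timestamps, c(0.25, 0.5))

  # empty trains: header-only file, empty list on read
  p2 <- withr::local_tempfile(fileext = ".csv")
  export_raster(list(spike_train(numeric(0), "e00", "w1", 1)), p2)
  expect_equal(nrow(read.csv(p2)), 0)
  expect_length(read_raster(p2), 0)
})
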