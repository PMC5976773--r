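test_that("synth_params validates its invariants", {
  expect_s3_class(synth_params(), "synth_params")
  expect_error(synth_params(wells_per_group = 0), "wells_per_group")
  expect_error(synth_params(mea_effect = 0), "mea_effect")
  expect_error(synth_params(mea_effect = 1.2), "mea_effect")
  expect_error(synth_params(noise_sd = -1), "noise_sd")
  expect_error(synth_params(ca_tau_s = 0), "ca_tau_s")
  # rate 0 is a legitimate empty process
  expect_silent(synth_params(mea_rate_control = 0))
})

test_that("MEA well simulation is deterministic and honours the empty process", {
  p <- synth_params(seed = 5)
  a <- simulate_mea_well(p, "control", duration_s = 1, n_electrodes = 4, seed = 5)
  b <- simulate_mea_well(p, "control", duration_s = 1, n_electrodes = 4, seed = 5)
  expect_identical(a, b)

  p0 <- synth_params(seed = 5, mea_rate_control = 0, mea_silent_frac = 0)
  z <- simulate_mea_well(p0, "control", duration_s = 1, n_electrodes = 3, seed = 5)
  expect_true(all(lengths(z$truth$spike_times) == 0))
  # traces are pure Gaussian noise: no waveform-scale deflections
  expect_lt(max(abs(z$traces[[1]]$samples)) / p0$noise_sd, 6.5)

  expect_error(simulate_mea_well(p, "control", duration_s = 1e-4),
               "duration")
})

test_that("ground-truth spike counts follow the Poisson law", {
  p <- synth_params(seed = 1, mea_silent_frac = 0)
  counts <- sapply(1:300, function(s) {
    w <- simulate_mea_well(p, "control", duration_s = 600, n_electrodes = 1,
                           seed = s, keep_traces = FALSE)
    length(w$truth$spike_times[[1]])
  })
  # rate 1 Hz x 600 s: mean within 3 sd(mean) of 600
  expect_lt(abs(mean(counts) - 600), 3 * sqrt(600 / 300))
  # chi-square dispersion: index of dispersion near 1
  disp <- (length(counts) - 1) * var(counts) / mean(counts)
  expect_gt(disp, qchisq(0.005, length(counts) - 1))
  expect_lt(disp, qchisq(0.995, length(counts) - 1))
  # ground-truth times sorted and inside the recording
  w <- simulate_mea_well(p, "control", duration_s = 10, n_electrodes = 2, seed = 2)
  for (tt in w$truth$spike_times) {
    expect_false(is.unsorted(tt))
    if (length(tt)) expect_true(all(tt >= 0 & tt <= 10))
  }
})

test_that("silent-electrode fraction is honoured", {
  p <- synth_params(seed = 9)
  w <- simulate_mea_well(p, "control", duration_s = 1, n_electrodes = 64,
                         seed = 9, keep_traces = FALSE)
  expect_equal(sum(!w$truth$active), 32)
  expect_true(all(lengths(w$truth$spike_times[!w$truth$active]) == 0))
})

test_that("calcium simulation constructs traces as documented", {
  p <- synth_params(seed = 2, ca_noise_sd = 0)
  # single event at t = 300, zero noise: maximum at sample index 301
  sim <- simulate_calcium_cell(p, "control", seed = 2, event_times = 300)
  expect_equal(which.max(sim$trace$values), 301)
  expect_equal(max(sim$trace$values), p$ca_baseline + p$ca_amplitude)

  # rate 0: flat noisy baseline, empty ground truth
  p0 <- synth_params(seed = 2, ca_event_rate_control = 0)
  s0 <- simulate_calcium_cell(p0, "control", seed = 2)
  expect_length(s0$truth$event_times, 0)
  expect_lt(max(abs(s0$trace$values - p0$ca_baseline)), 5 * p0$ca_noise_sd)

  # determinism
  expect_identical(simulate_calcium_cell(p, "case", seed = 7),
                   simulate_calcium_cell(p, "case", seed = 7))
  expect_error(synth_params(ca_amplitude = -1), "ca_amplitude")
})

test_that("scratch series mean curves encode the divergence-day design", {
  p <- synth_params(seed = 3)
  ctrl <- simulate_scratch_series(p, "control", seed = 3)
  case <- simulate_scratch_series(p, "case", seed = 4)
  mc <- attr(ctrl, "mean_curve")
  ma <- attr(case, "mean_curve")
  expect_equal(mc[1], 0)                       # day 0: scratch just made
  expect_equal(ma[1:5], mc[1:5])               # identical through day 4
  expect_equal(ma[4], mc[4])                   # day 3 explicitly equal
  expect_lt(ma[11], mc[11])                    # day 10: control strictly greater
  expect_true(all(diff(mc) > 0) && all(diff(ma) > 0))
  expect_true(all(ctrl$count >= 0) && all(ctrl$count == round(ctrl$count)))
})

test_that("injected effects appear at the stated ratio in ground truth", {
  p <- synth_params(seed = 1, mea_silent_frac = 0)
  n_grp <- function(group, seeds) sapply(seeds, function(s)
    sum(lengths(simulate_mea_well(p, group, duration_s = 60, n_electrodes = 8,
                                  seed = s, keep_traces = FALSE)$truth$spike_times)))
  r <- mean(n_grp("case", 1:40)) / mean(n_grp("control", 101:140))
  expect_lt(abs(r - p$mea_effect), 0.1)
})

test_that("simulate_cohort is deterministic, writes the CSV layout, and refuses overwrite", {
  p <- synth_params(seed = 11, wells_per_group = 3, cells_per_well = 2,
                    duration_s = 5)
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$design), 6)
  expect_setequal(unique(c1$design$group), c("case", "control"))

  dir <- withr::local_tempdir()
  out <- file.path(dir, "cohort")
  simulate_cohort(p, out_dir = out)
  expect_true(file.exists(file.path(out, "design.csv")))
  expect_true(file.exists(file.path(out, "mea_counts.csv")))
  expect_true(file.exists(file.path(out, "scratch_counts.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  expect_length(list.files(out, pattern = "^ca_.*\\.csv$"), 6)
  expect_error(simulate_cohort(p, out_dir = out), "force")
  expect_silent(simulate_cohort(p, out_dir = out, force = TRUE))

  # trace fidelity also writes per-well voltage tables
  pt <- synth_params(seed = 11, wells_per_group = 1, cells_per_well = 1,
                     duration_s = 0.5)
  out2 <- file.path(dir, "traces")
  simulate_cohort(pt, fidelity = "traces", out_dir = out2)
  mea_files <- list.files(out2, pattern = "^mea_.*\\.csv$", full.names = TRUE)
  expect_length(mea_files, 2)
  head_tab <- read.csv(mea_files[1], nrows = 2)
  expect_true(all(c("time_s", "e00", "e63") %in% names(head_tab)))
})
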