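# the worked seven-sample trace used throughout: one clean transient
worked <- fluorescence_trace(c(0, 0, 1, 3, 1, 0, 0), dt = 1,
                             background_subtracted = TRUE)

test_that("background subtraction is elementwise with provenance", {
  tr <- fluorescence_trace(c(5, 6, 5))
  expect_false(tr$background_subtracted)
  b0 <- background_subtract(tr, 0)
  expect_equal(b0$values, c(5, 6, 5))
  expect_true(b0$background_subtracted)
  expect_equal(background_subtract(tr, 5)$values, c(0, 1, 0))
  expect_equal(background_subtract(tr, c(5, 6, 5))$values, c(0, 0, 0))
  expect_error(background_subtract(tr, c(1, 2)), "length")
})

test_that("candidate delimitation handles the worked trace and degenerate shapes", {
  cand <- find_candidate_peaks(worked)
  expect_equal(nrow(cand), 1)
  # strict descent from the maximum stalls at the zero plateau on each side
  expect_equal(unname(cand[1, ]), c(2L, 4L, 6L))

  expect_equal(nrow(find_candidate_peaks(fluorescence_trace(1:10, background_subtracted = TRUE))), 0)
  expect_equal(nrow(find_candidate_peaks(fluorescence_trace(rep(2, 10), background_subtracted = TRUE))), 0)
  expect_warning(find_candidate_peaks(fluorescence_trace(c(0, 1, 0))), "background")

  # two well-separated triangular pulses are delimited independently
  two <- fluorescence_trace(c(0, 1, 2, 1, 0, 0, 0, 1, 3, 1, 0), background_subtracted = TRUE)
  cand2 <- find_candidate_peaks(two)
  expect_equal(nrow(cand2), 2)
  expect_equal(unname(cand2[, "peak"]), c(3L, 9L))

  # plateau maxima collapse to the midpoint (left of centre when even)
  plat3 <- find_candidate_peaks(c(0, 1, 2, 2, 2, 1, 0))
  expect_equal(unname(plat3[, "peak"]), 4L)
  plat2 <- find_candidate_peaks(c(0, 1, 2, 2, 1, 0))
  expect_equal(unname(plat2[, "peak"]), 3L)
})

test_that("candidate delimitation equals brute-force enumeration on random traces", {
  set.seed(11)
  for (i in 1:200) {
    y <- random_short_trace(sample(3:80, 1))
    expect_identical(find_candidate_peaks(y), oracle_peaks(y))
  }
})

test_that("triangle relevance area follows the shoelace geometry", {
  tri <- c(2L, 4L, 6L)
  expect_equal(peak_relevance_area(worked, tri), 6.0)
  # vertical offset and time shift leave it unchanged
  shifted <- fluorescence_trace(worked$values + 100, dt = 1, background_subtracted = TRUE)
  expect_equal(peak_relevance_area(shifted, tri), 6.0)
  # doubling dt doubles the area
  wide <- fluorescence_trace(worked$values, dt = 2, background_subtracted = TRUE)
  expect_equal(peak_relevance_area(wide, tri), 12.0)
  # collinear vertices give zero, not an error
  expect_equal(peak_relevance_area(c(0, 1, 2, 3, 4), c(1L, 3L, 5L)), 0)
  expect_error(peak_relevance_area(worked, c(4L, 2L, 6L)), "triple")
  # under-curve alternative: area above the chord between the two minima
  expect_equal(peak_relevance_area(worked, tri, method = "under_curve"),
               sum(c(0, 1, 3, 1, 0)) - 0)
})

test_that("the literal relevance rule marks the worked peak relevant at the hand threshold", {
  calls <- call_relevant_peaks(worked)
  expect_equal(nrow(calls), 1)
  mu <- mean(worked$values)
  sd_pop <- sqrt(mean((worked$values - mu)^2))
  expect_equal(attr(calls, "threshold"), mu + sd_pop)
  expect_equal(attr(calls, "threshold"), 1.7445, tolerance = 1e-4)
  expect_equal(calls$relevance_area, 6.0)
  expect_true(calls$is_relevant)
})

test_that("alternative rules and multipliers behave as documented", {
  # the peak-population rule can never keep a sole candidate (SD of one area is 0)
  pp <- call_relevant_peaks(worked, rule = "peak_population")
  expect_false(pp$is_relevant)
  # sd_only drops the mean term
  so <- call_relevant_peaks(worked, rule = "sd_only")
  expect_equal(attr(so, "threshold"), sqrt(mean((worked$values - mean(worked$values))^2)))
  expect_true(so$is_relevant)
  # raising the multiplier never increases the relevant count
  p <- synth_params(seed = 3)
  sim <- simulate_calcium_cell(p, "control", seed = 3)
  n_rel <- sapply(c(0.5, 1, 2, 4, 8), function(m)
    sum(call_relevant_peaks(sim$trace, sd_multiplier = m)$is_relevant))
  expect_true(all(diff(n_rel) <= 0))
  # constant trace: no candidates, empty call set
  const <- fluorescence_trace(rep(1, 20), background_subtracted = TRUE)
  expect_equal(nrow(call_relevant_peaks(const)), 0)
  # dt != 1 under the literal rule warns about the unit mismatch
  odd <- fluorescence_trace(c(0, 1, 0), dt = 0.5, background_subtracted = TRUE)
  expect_warning(call_relevant_peaks(odd), "dt != 1")
})

test_that("event frequency and the active-cell filter follow their definitions", {
  none <- call_relevant_peaks(fluorescence_trace(rep(0, 10), background_subtracted = TRUE))
  ef0 <- event_frequency(none, 600)
  expect_equal(ef0$freq_per_min, 0)
  expect_false(ef0$active)

  calls <- data.frame(is_relevant = rep(c(TRUE, FALSE), c(12, 3)))
  ef <- event_frequency(calls, 600, roi_id = "r")
  expect_equal(ef$n_relevant_events, 12)
  expect_equal(ef$freq_per_min, 1.2)
  expect_true(ef$active)
  expect_error(event_frequency(calls, 0), "positive")

  res <- rbind(ef0, ef)
  expect_message(act <- active_cell_filter(res), "excluded 1")
  expect_equal(nrow(act), 1)
  expect_true(all(act$active))
  expect_identical(suppressMessages(active_cell_filter(act)), act)
  expect_equal(nrow(suppressMessages(active_cell_filter(res[FALSE, ]))), 0)
})

test_that("called event rate tracks simulator ground truth within 10%", {
  # spec world: amplitude / noise = 10 at the control rate (2 events/min)
  p10 <- synth_params(seed = 1, ca_noise_sd = 10)
  ratio <- function(params, group, seeds) {
    got <- sapply(seeds, function(s) {
      sim <- simulate_calcium_cell(params, group, seed = s)
      det <- ca_detect_trace(sim$trace)
      c(called = det$summary$n_relevant_events, true = length(sim$truth$event_times))
    })
    sum(got["called", ]) / sum(got["true", ])
  }
  expect_lt(abs(ratio(p10, "control", 1:60) - 1), 0.1)
  # default (high SNR) world, both groups
  p <- synth_params(seed = 1)
  expect_lt(abs(ratio(p, "control", 1:60) - 1), 0.1)
  expect_lt(abs(ratio(p, "case", 101:160) - 1), 0.1)
})
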