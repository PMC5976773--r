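#' Synthetic cohort parameters
#'
#' One object fixing every knob of the seeded generator. Defaults encode the
#' cohort this pipeline targets: six case (ASD) iPSC lines and five control
#' lines, 16 wells per group in three independent replicates, 10-minute MEA
#' recordings at 12.5 kHz on 8 x 8 electrode grids, 10-minute calcium traces
#' at 1 Hz, and a 10-day scratch time course whose case/control divergence
#' begins after day 4. Effect factors multiply case rates (0.5 = the 50 %
#' suppression the assays are powered to detect).
#'
#' Control-level rates are free parameters (no instrument data ship with the
#' package); defaults are field-typical: 1 spike/s per active electrode,
#' calcium transients at 2 events/min with resting fluorescence F0 = 50 a.u.,
#' transient amplitude 100 a.u. (dF/F0 = 2) and decay tau = 2 s, and scratch
#' reinvasion growing by 12 objects/day in controls.
#'
#' @param seed Integer seed; the same `synth_params` yields byte-identical
#'   output.
#' @param n_case_lines,n_control_lines Number of iPSC lines per group.
#' @param wells_per_group Wells per group (default 16).
#' @param replicates Independent biological replicates (default 3).
#' @param duration_s MEA recording duration, seconds.
#' @param mea_fs MEA sampling rate, Hz.
#' @param mea_rate_control Control firing rate per active electrode, spikes/s.
#' @param mea_effect Multiplicative case rate factor, in (0, 1].
#' @param mea_silent_frac Fraction of electrodes with no unit on them.
#' @param mea_amp_snr Spike trough amplitude as a multiple of `noise_sd`.
#' @param noise_sd MEA noise SD, uV.
#' @param ca_duration_s,ca_dt Calcium recording duration and sampling
#'   interval, seconds.
#' @param ca_event_rate_control Control calcium event rate, events/min.
#' @param ca_effect Multiplicative case factor, in (0, 1].
#' @param ca_baseline,ca_amplitude,ca_noise_sd,ca_tau_s Calcium trace shape:
#'   resting fluorescence, transient amplitude, noise SD (a.u.) and decay
#'   time constant (s).
#' @param cells_per_well Calcium ROIs simulated per well.
#' @param scratch_days Last imaging day (days 0..`scratch_days`).
#' @param scratch_rate_control Control reinvasion growth, objects/day.
#' @param scratch_effect Case growth factor after the divergence day.
#' @param scratch_divergence_day Day after which case growth slows.
#' @param line_cv Coefficient of variation of per-line rate multipliers
#'   (log-normal); 0 (default) means lines within a group are exchangeable.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(seed = 1L,
                         n_case_lines = 6L, n_control_lines = 5L,
                         wells_per_group = 16L, replicates = 3L,
                         duration_s = 600, mea_fs = 12500,
                         mea_rate_control = 1.0, mea_effect = 0.5,
                         mea_silent_frac = 0.5, mea_amp_snr = 8,
                         noise_sd = 3,
                         ca_duration_s = 600, ca_dt = 1,
                         ca_event_rate_control = 2.0, ca_effect = 0.5,
                         ca_baseline = 50, ca_amplitude = 100,
                         ca_noise_sd = 5, ca_tau_s = 2,
                         cells_per_well = 10L,
                         scratch_days = 10L, scratch_rate_control = 12,
                         scratch_effect = 0.5, scratch_divergence_day = 4L,
                         line_cv = 0) {
  p <- list(seed = as.integer(seed), n_case_lines = as.integer(n_case_lines),
            n_control_lines = as.integer(n_control_lines),
            wells_per_group = as.integer(wells_per_group),
            replicates = as.integer(replicates),
            duration_s = duration_s, mea_fs = mea_fs,
            mea_rate_control = mea_rate_control, mea_effect = mea_effect,
            mea_silent_frac = mea_silent_frac, mea_amp_snr = mea_amp_snr,
            noise_sd = noise_sd,
            ca_duration_s = ca_duration_s, ca_dt = ca_dt,
            ca_event_rate_control = ca_event_rate_control, ca_effect = ca_effect,
            ca_baseline = ca_baseline, ca_amplitude = ca_amplitude,
            ca_noise_sd = ca_noise_sd, ca_tau_s = ca_tau_s,
            cells_per_well = as.integer(cells_per_well),
            scratch_days = as.integer(scratch_days),
            scratch_rate_control = scratch_rate_control,
            scratch_effect = scratch_effect,
            scratch_divergence_day = as.integer(scratch_divergence_day),
            line_cv = line_cv)
  counts <- c("n_case_lines", "n_control_lines", "wells_per_group",
              "replicates", "cells_per_well")
  for (nm in counts)
    if (p[[nm]] < 1L) stop("synth_params: '", nm, "' must be >= 1")
  for (nm in c("noise_sd", "ca_amplitude", "ca_tau_s", "duration_s",
               "ca_duration_s", "mea_fs"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) stop("synth_params: '", nm, "' must be > 0")
  # rate 0 is a valid (empty) Poisson process; calcium noise may be 0 for
  # noise-free construction tests
  for (nm in c("mea_rate_control", "ca_event_rate_control",
               "scratch_rate_control", "ca_noise_sd"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) stop("synth_params: '", nm, "' must be >= 0")
  for (nm in c("mea_effect", "ca_effect", "scratch_effect"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1)
      stop("synth_params: '", nm, "' must be in (0, 1]")
  if (p$mea_silent_frac < 0 || p$mea_silent_frac >= 1)
    stop("synth_params: 'mea_silent_frac' must be in [0, 1)")
  if (p$line_cv < 0) stop("synth_params: 'line_cv' must be >= 0")
  structure(p, class = "synth_params")
}

group_rate_factor <- function(params, group_label, what = c("mea", "ca")) {
  what <- match.arg(what)
  eff <- if (what == "mea") params$mea_effect else params$ca_effect
  if (identical(group_label, "case")) eff else 1
}

# log-normal per-line multiplier with mean 1 and CV line_cv
line_multiplier <- function(line_cv, n = 1L) {
  if (line_cv <= 0) return(rep(1, n))
  s2 <- log(1 + line_cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Biphasic extracellular spike template
#'
#' Negative trough followed by a positive rebound (trough:peak amplitude
#' 2:1), total 1.6 ms — the canonical extracellular waveform shape. Built
#' from two half-sine lobes (trough 0.6 ms, rebound 1.0 ms).
#'
#' @param fs Sampling rate, Hz.
#' @param amplitude Trough depth, uV (positive number).
#' @param total_ms Total template duration, ms.
#' @return Numeric vector of template samples.
#' @export
spike_waveform <- function(fs = 12500, amplitude = 24, total_ms = 1.6) {
  if (total_ms <= 0) stop("spike_waveform: 'total_ms' must be > 0")
  n <- round(total_ms / 1000 * fs)
  if (n < 2L) stop("spike_waveform: sampling rate too low to hold one waveform")
  n1 <- max(1L, round(n * 0.6 / 1.6))
  n2 <- n - n1
  c(-amplitude * sin(pi * seq_len(n1) / (n1 + 1)),
    if (n2 > 0) amplitude / 2 * sin(pi * seq_len(n2) / (n2 + 1)))
}

#' Simulate one MEA well
#'
#' Generates 64 electrode traces: Gaussian noise plus biphasic spike
#' waveforms inserted at homogeneous-Poisson times, with the case rate scaled
#' by `mea_effect`. A fraction of electrodes (`mea_silent_frac`, chosen at
#' random) is silent. Ground-truth spike times (waveform trough times) are
#' returned per electrode.
#'
#' With default parameters a full well holds 64 x 7.5e6 samples (~3.8 GB);
#' pass a smaller `duration_s` or `n_electrodes` for in-memory work, or use
#' [mea_detect_well()] which streams electrode by electrode.
#'
#' @param params A [synth_params()]. Its `seed` is used unless `seed` is
#'   given.
#' @param group_label `"case"` or `"control"`.
#' @param duration_s Recording duration (default `params$duration_s`).
#' @param n_electrodes Number of electrodes (default 64, the 8 x 8 grid).
#' @param well_id Label stamped on the traces.
#' @param seed Optional override seed.
#' @param keep_traces If `FALSE`, traces are not retained (ground truth
#'   only) — used by count-level cohort simulation.
#' @return List with `traces` (list of [voltage_trace()], or `NULL`),
#'   `truth` (list: `spike_times` per electrode, `rate_hz`, `active`
#'   logical), `well_id`, `group`.
#' @export
simulate_mea_well <- function(params, group_label, duration_s = params$duration_s,
                              n_electrodes = 64L, well_id = "w01",
                              seed = NULL, keep_traces = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  group_label <- match.arg(group_label, c("case", "control"))
  wf <- spike_waveform(params$mea_fs, params$mea_amp_snr * params$noise_sd)
  n <- round(duration_s * params$mea_fs)
  if (n < length(wf))
    stop("simulate_mea_well: duration too short to hold one spike waveform")
  if (!is.null(seed)) set.seed(seed)
  rate <- params$mea_rate_control * group_rate_factor(params, group_label, "mea")
  n_silent <- round(params$mea_silent_frac * n_electrodes)
  silent <- seq_len(n_electrodes) %in% sample.int(n_electrodes, n_silent)
  trough_off <- which.min(wf) - 1L
  traces <- if (keep_traces) vector("list", n_electrodes) else NULL
  times <- vector("list", n_electrodes)
  eids <- sprintf("e%02d", seq_len(n_electrodes) - 1L)
  for (e in seq_len(n_electrodes)) {
    erate <- if (silent[e]) 0 else rate
    nev <- if (erate > 0) stats::rpois(1, erate * duration_s) else 0L
    # start indices such that the whole waveform fits in the recording
    starts <- if (nev > 0) sort(sample.int(n - length(wf) + 1L, nev, replace = TRUE)) else integer(0)
    times[[e]] <- (starts - 1L + trough_off) / params$mea_fs
    if (keep_traces) {
      x <- stats::rnorm(n, 0, params$noise_sd)
      for (s in starts) {
        idx <- s:(s + length(wf) - 1L)
        x[idx] <- x[idx] + wf
      }
      traces[[e]] <- voltage_trace(x, fs = params$mea_fs, electrode_id = eids[e],
                                   well_id = well_id)
    } else {
      # keep RNG stream aligned across fidelity levels is not required;
      # count fidelity only draws event times
    }
  }
  names(times) <- eids
  list(traces = traces,
       truth = list(spike_times = times, rate_hz = rate, active = !silent),
       well_id = well_id, group = group_label)
}

#' Simulate one calcium-imaging ROI
#'
#' Resting fluorescence plus optional linear drift, Gaussian noise, and
#' calcium transients (instantaneous rise, single-exponential decay) at
#' homogeneous-Poisson times, with case rates scaled by `ca_effect`.
#'
#' @inheritParams simulate_mea_well
#' @param roi_id ROI label.
#' @param drift_per_s Linear baseline drift, a.u./s (default 0).
#' @param event_times Optional fixed transient times (seconds), bypassing the
#'   Poisson draw — for constructing known traces.
#' @return List with `trace` (a [fluorescence_trace()]) and `truth`
#'   (`event_times` seconds, `rate_per_min`).
#' @export
simulate_calcium_cell <- function(params, group_label, roi_id = "roi_0",
                                  well_id = NA_character_, drift_per_s = 0,
                                  seed = NULL, event_times = NULL) {
  stopifnot(inherits(params, "synth_params"))
  group_label <- match.arg(group_label, c("case", "control"))
  if (params$ca_tau_s <= 0 || params$ca_amplitude <= 0)
    stop("simulate_calcium_cell: tau and amplitude must be positive")
  if (!is.null(seed)) set.seed(seed)
  dur <- params$ca_duration_s
  t <- seq(0, dur - params$ca_dt, by = params$ca_dt)
  rate_min <- params$ca_event_rate_control * group_rate_factor(params, group_label, "ca")
  ev <- if (!is.null(event_times)) {
    sort(event_times)
  } else {
    sort(stats::runif(stats::rpois(1, rate_min * dur / 60), 0, dur))
  }
  y <- params$ca_baseline + drift_per_s * t +
    stats::rnorm(length(t), 0, params$ca_noise_sd)
  for (e in ev) {
    idx <- which(t >= e)
    y[idx] <- y[idx] + params$ca_amplitude * exp(-(t[idx] - e) / params$ca_tau_s)
  }
  list(trace = fluorescence_trace(y, dt = params$ca_dt, roi_id = roi_id,
                                  well_id = well_id, group = group_label,
                                  background_subtracted = TRUE),
       truth = list(event_times = ev, rate_per_min = rate_min))
}

# mean reinvasion count curve: 0 at day 0, linear growth, case growth slowed
# after the divergence day
scratch_mean_curve <- function(params, group_label, days = 0:params$scratch_days) {
  r <- params$scratch_rate_control
  d0 <- params$scratch_divergence_day
  mu <- r * days
  if (identical(group_label, "case")) {
    after <- days > d0
    mu[after] <- r * d0 + params$scratch_effect * r * (days[after] - d0)
  }
  mu
}

#' Simulate one scratch-assay well
#'
#' Daily reinvasion counts in the standardized ROI: Poisson draws around a
#' monotone-increasing mean curve that starts at 0 on day 0 (scratch just
#' made). Case and control mean curves are identical through
#' `scratch_divergence_day`; the case curve grows more slowly thereafter
#' (growth multiplied by `scratch_effect`).
#'
#' @inheritParams simulate_mea_well
#' @return Data frame (class `scratch_series`): `well`, `group`, `day`,
#'   `count`, with the generating mean in attribute `"mean_curve"`.
#' @export
simulate_scratch_series <- function(params, group_label, well_id = "w01",
                                    seed = NULL) {
  stopifnot(inherits(params, "synth_params"))
  group_label <- match.arg(group_label, c("case", "control"))
  if (!is.null(seed)) set.seed(seed)
  days <- 0:params$scratch_days
  mu <- scratch_mean_curve(params, group_label, days)
  counts <- integer(length(days))
  pos <- mu > 0
  counts[pos] <- stats::rpois(sum(pos), mu[pos])
  out <- data.frame(well = well_id, group = group_label, day = days,
                    count = counts, stringsAsFactors = FALSE)
  attr(out, "mean_curve") <- mu
  class(out) <- c("scratch_series", "data.frame")
  out
}

#' Build the cohort design table
#'
#' Assigns `wells_per_group` wells per group round-robin to that group's
#' lines, cycling the replicate label.
#'
#' @param params A [synth_params()].
#' @return Data frame: `well`, `line`, `group`, `replicate`.
#' @export
cohort_design <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  one_group <- function(group, n_lines) {
    lines <- sprintf("%s_%d", group, seq_len(n_lines))
    w <- seq_len(params$wells_per_group)
    data.frame(
      well = sprintf("%s_w%02d", group, w),
      line = lines[(w - 1L) %% n_lines + 1L],
      group = group,
      replicate = (w - 1L) %/% ceiling(params$wells_per_group / params$replicates) + 1L,
      stringsAsFactors = FALSE)
  }
  rbind(one_group("control", params$n_control_lines),
        one_group("case", params$n_case_lines))
}

#' Simulate a full cohort
#'
#' Generates every assay for the cohort laid out by [cohort_design()],
#' deterministically from `params$seed`. Two fidelity levels:
#'
#' * `"counts"` (default): MEA wells carry ground-truth spike times only
#'   (the distribution perfect detection would return); calcium and scratch
#'   arms are simulated in full. Fast enough for repeated power simulation.
#' * `"traces"`: MEA wells additionally carry full voltage traces. A
#'   default-size cohort at trace fidelity does not fit in memory; restrict
#'   `duration_s` or `wells_per_group` first.
#'
#' When `out_dir` is given, the spec'd CSV layout is written: one MEA well
#' CSV (`mea_<well>.csv`, columns `time_s, e00...`) per well at trace
#' fidelity or a single `mea_counts.csv` at count fidelity, one calcium CSV
#' per well (`ca_<well>.csv`: `time_s, roi_0...`), `scratch_counts.csv`,
#' `design.csv`, and `ground_truth.json`.
#'
#' @param params A [synth_params()].
#' @param fidelity `"counts"` or `"traces"`.
#' @param out_dir Optional output directory.
#' @param force Overwrite an existing non-empty `out_dir`.
#' @param line_factors Optional named per-line rate multipliers (defaults to
#'   draws controlled by `params$line_cv`).
#' @return List: `design`, `mea` (per-well list from [simulate_mea_well()]),
#'   `calcium` (per-well list of [simulate_calcium_cell()] results),
#'   `scratch` (list of [simulate_scratch_series()]), `params`.
#' @export
simulate_cohort <- function(params, fidelity = c("counts", "traces"),
                            out_dir = NULL, force = FALSE,
                            line_factors = NULL) {
  stopifnot(inherits(params, "synth_params"))
  fidelity <- match.arg(fidelity)
  if (!is.null(out_dir) && dir.exists(out_dir) &&
      length(dir(out_dir, all.files = TRUE, no.. = TRUE)) > 0 && !force)
    stop("simulate_cohort: output path '", out_dir,
         "' exists and is not empty; use force = TRUE to overwrite")
  set.seed(params$seed)
  design <- cohort_design(params)
  lines <- unique(design$line)
  if (is.null(line_factors)) {
    line_factors <- stats::setNames(line_multiplier(params$line_cv, length(lines)), lines)
  }
  keep <- identical(fidelity, "traces")
  mea <- vector("list", nrow(design))
  ca <- vector("list", nrow(design))
  scr <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    w <- design$well[i]
    grp <- design$group[i]
    lf <- line_factors[[design$line[i]]]
    pw <- params
    pw$mea_rate_control <- params$mea_rate_control * lf
    pw$ca_event_rate_control <- params$ca_event_rate_control * lf
    pw$scratch_rate_control <- params$scratch_rate_control * lf
    class(pw) <- "synth_params"
    mea[[i]] <- simulate_mea_well(pw, grp, well_id = w, keep_traces = keep)
    ca[[i]] <- lapply(seq_len(params$cells_per_well) - 1L, function(k)
      simulate_calcium_cell(pw, grp, roi_id = sprintf("roi_%d", k), well_id = w))
    scr[[i]] <- simulate_scratch_series(pw, grp, well_id = w)
  }
  names(mea) <- names(ca) <- names(scr) <- design$well
  cohort <- list(design = design, mea = mea, calcium = ca, scratch = scr,
                 params = params, line_factors = line_factors,
                 fidelity = fidelity)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$design, file.path(out_dir, "design.csv"), row.names = FALSE)
  # MEA
  if (identical(cohort$fidelity, "traces")) {
    for (w in names(cohort$mea)) {
      tr <- cohort$mea[[w]]$traces
      fs <- tr[[1]]$fs
      tab <- data.frame(time_s = (seq_along(tr[[1]]$samples) - 1) / fs)
      for (v in tr) tab[[v$electrode_id]] <- v$samples
      utils::write.csv(tab, file.path(out_dir, sprintf("mea_%s.csv", w)),
                       row.names = FALSE)
    }
  } else {
    rows <- do.call(rbind, lapply(names(cohort$mea), function(w) {
      st <- cohort$mea[[w]]$truth$spike_times
      data.frame(well = w, electrode = names(st),
                 n_spikes = vapply(st, length, integer(1)),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, file.path(out_dir, "mea_counts.csv"), row.names = FALSE)
  }
  # calcium: one CSV per well
  for (w in names(cohort$calcium)) {
    cells <- cohort$calcium[[w]]
    tab <- data.frame(time_s = (seq_along(cells[[1]]$trace$values) - 1) *
                        cells[[1]]$trace$dt)
    for (c_ in cells) tab[[c_$trace$roi_id]] <- c_$trace$values
    utils::write.csv(tab, file.path(out_dir, sprintf("ca_%s.csv", w)),
                     row.names = FALSE)
  }
  scr <- do.call(rbind, lapply(cohort$scratch, function(s) as.data.frame(s)))
  utils::write.csv(scr[, c("well", "day", "count")],
                   file.path(out_dir, "scratch_counts.csv"), row.names = FALSE)
  truth <- list(
    mea_spike_times = lapply(cohort$mea, function(m) m$truth$spike_times),
    ca_event_times = lapply(cohort$calcium, function(cs)
      lapply(stats::setNames(cs, vapply(cs, function(x) x$trace$roi_id, character(1))),
             function(x) x$truth$event_times)),
    effects = list(mea_effect = cohort$params$mea_effect,
                   ca_effect = cohort$params$ca_effect,
                   scratch_effect = cohort$params$scratch_effect,
                   scratch_divergence_day = cohort$params$scratch_divergence_day),
    seed = cohort$params$seed)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
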