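#' Construct a voltage trace
#'
#' Container for one electrode's extracellular voltage signal. Samples are in
#' microvolts; time of sample `i` is `(i - 1) / fs` seconds.
#'
#' @param samples Numeric vector of voltage samples (uV). Must be finite and
#'   non-empty.
#' @param fs Sampling rate in Hz (default 12500, the acquisition rate of the
#'   Maestro-class MEA systems this pipeline targets).
#' @param electrode_id Electrode label, e.g. `"e00"` ... `"e63"` on the 8 x 8
#'   grid.
#' @param well_id Plate well label.
#' @param filtered Logical provenance flag: has the software band-pass been
#'   applied? [detect_spikes()] warns when it is `FALSE`.
#' @return An object of class `voltage_trace`.
#' @seealso [bandpass_filter()], [detect_spikes()]
#' @export
voltage_trace <- function(samples, fs = 12500, electrode_id = NA_character_,
                          well_id = NA_character_, filtered = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("voltage_trace: 'samples' must be non-empty")
  if (!all(is.finite(samples))) stop("voltage_trace: all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("voltage_trace: 'fs' must be a single positive number")
  structure(
    list(samples = samples, fs = fs, electrode_id = electrode_id,
         well_id = well_id, filtered = isTRUE(filtered)),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %s/%s: %d samples @ %g Hz (%.3f s)%s\n",
              x$well_id, x$electrode_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (x$filtered) ", band-pass filtered" else ""))
  invisible(x)
}

#' Band-pass filter specification
#'
#' First-order Butterworth band-pass, the software filter applied to raw MEA
#' traces before spike detection. Only `order = 1` is supported; the family
#' is fixed.
#'
#' @param low_hz Lower cutoff (-3 dB point), Hz. Default 200.
#' @param high_hz Upper cutoff (-3 dB point), Hz. Default 2500.
#' @param order Filter order; must be 1.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 200, high_hz = 2500, order = 1L) {
  if (!isTRUE(order == 1)) stop("filter_spec: only first-order (order = 1) Butterworth is supported")
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 || high_hz <= low_hz)
    stop("filter_spec: need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = 1L,
                 family = "butterworth"),
            class = "filter_spec")
}

# Bilinear-transform design of the first-order Butterworth band-pass.
# Analog prototype H(s) = B s / (s^2 + B s + w0^2), with the two cutoffs
# prewarped so the digital -3 dB points land exactly at low_hz / high_hz.
butter_bandpass_coefs <- function(low_hz, high_hz, fs) {
  if (high_hz >= fs / 2)
    stop(sprintf("band-pass design: high cutoff %g Hz is at or above Nyquist (%g Hz)",
                 high_hz, fs / 2))
  c2 <- 2 * fs
  w1 <- c2 * tan(pi * low_hz / fs)
  w2 <- c2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0sq <- w1 * w2
  a0 <- c2 * c2 + bw * c2 + w0sq
  b <- bw * c2 * c(1, 0, -1) / a0
  a <- c(1, (-2 * c2 * c2 + 2 * w0sq) / a0, (c2 * c2 - bw * c2 + w0sq) / a0)
  list(b = b, a = a)
}

#' Frequency response of the band-pass filter
#'
#' Exact digital amplitude response `|H(e^{i 2 pi f / fs})|` of the filter
#' that [bandpass_filter()] applies. By prewarped bilinear design this equals
#' the analog first-order band-pass response evaluated at the warped frequency
#' `2 fs tan(pi f / fs)`, so the gain at `low_hz` and `high_hz` is exactly
#' -3.01 dB.
#'
#' @param f Frequencies (Hz) at which to evaluate the response.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of amplitude ratios (1 = unity gain).
#' @export
bandpass_gain <- function(f, spec, fs = 12500) {
  co <- butter_bandpass_coefs(spec$low_hz, spec$high_hz, fs)
  z1 <- exp(-1i * 2 * pi * f / fs)
  num <- co$b[1] + co$b[2] * z1 + co$b[3] * z1^2
  den <- co$a[1] + co$a[2] * z1 + co$a[3] * z1^2
  Mod(num / den)
}

#' Apply the software band-pass filter
#'
#' Filters a raw trace with the first-order Butterworth band-pass (digital
#' biquad obtained by bilinear transform with frequency prewarping), zero
#' initial conditions. The output has the same length as the input; DC is
#' fully rejected and the gain at the two cutoffs is -3 dB.
#'
#' @param trace A [voltage_trace()].
#' @param spec A [filter_spec()]; defaults to the standard 200-2500 Hz setting.
#' @return A `voltage_trace` with `filtered = TRUE`.
#' @export
bandpass_filter <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "voltage_trace"), inherits(spec, "filter_spec"))
  co <- butter_bandpass_coefs(spec$low_hz, spec$high_hz, trace$fs)
  x <- trace$samples
  # FIR part with zero padding, then the AR recursion; both run in C.
  v <- stats::filter(c(0, 0, x), co$b, method = "convolution", sides = 1)
  v <- as.numeric(v[-(1:2)])
  y <- as.numeric(stats::filter(v, -co$a[2:3], method = "recursive"))
  out <- trace
  out$samples <- y
  out$filtered <- TRUE
  attr(out, "filter_spec") <- spec
  out
}

#' Rolling standard deviation
#'
#' Centered rolling sample SD used as the adaptive noise estimate for spike
#' thresholding. The half-width shrinks symmetrically near the edges; the two
#' boundary samples use the minimal two-sample window so the estimate is
#' defined everywhere. Output length equals input length.
#'
#' Computed from prefix sums (O(n)); sample (n-1) normalisation.
#'
#' @param x A [voltage_trace()] or numeric vector.
#' @param window_s Window length in seconds (trace input) — must hold at
#'   least 2 samples.
#' @param fs Sampling rate; taken from the trace if `x` is a `voltage_trace`.
#' @return Numeric vector of per-sample SD estimates.
#' @export
rolling_std <- function(x, window_s = 0.1, fs = NULL) {
  if (inherits(x, "voltage_trace")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("rolling_std: 'fs' required for plain numeric input")
  n <- length(x)
  w <- as.integer(round(window_s * fs))
  if (w < 2L) stop("rolling_std: window must hold at least 2 samples")
  if (w >= n) {
    if (w > n)
      message(sprintf("rolling_std: window (%d samples) longer than trace (%d); using global SD",
                      w, n))
    return(rep(stats::sd(x), n))
  }
  h <- max(1L, w %/% 2L)
  i <- seq_len(n)
  hi_w <- pmax(1L, pmin(h, pmin(i - 1L, n - i)))
  lo <- pmax(1L, i - hi_w)
  up <- pmin(n, i + hi_w)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  m <- up - lo + 1L
  s1 <- cs[up + 1L] - cs[lo]
  s2 <- cs2[up + 1L] - cs2[lo]
  sqrt(pmax((s2 - s1 * s1 / m) / (m - 1L), 0))
}

#' Spike threshold specification
#'
#' @param k Threshold multiplier on the rolling SD (default 5.25).
#' @param window_s Rolling-SD window, seconds (default 0.1 — long enough for
#'   a stable noise estimate, short against slow drift).
#' @param dead_time_s Minimum interval between detected spikes, seconds
#'   (default 0.001: refractory-period scale, suppresses double counts of one
#'   biphasic waveform).
#' @param polarity Which excursions count: `"both"` (threshold on |signal|,
#'   default), `"negative"` or `"positive"`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(k = 5.25, window_s = 0.1, dead_time_s = 0.001,
                           polarity = c("both", "negative", "positive")) {
  polarity <- match.arg(polarity)
  if (!is.finite(k) || k <= 0) stop("threshold_spec: 'k' must be positive")
  if (!is.finite(window_s) || window_s <= 0) stop("threshold_spec: 'window_s' must be positive")
  if (!is.finite(dead_time_s) || dead_time_s < 0) stop("threshold_spec: 'dead_time_s' must be >= 0")
  structure(list(k = k, window_s = window_s, dead_time_s = dead_time_s,
                 polarity = polarity),
            class = "threshold_spec")
}

#' Construct a spike train
#'
#' @param timestamps Spike times in seconds, sorted ascending.
#' @param electrode_id,well_id Labels.
#' @param duration_s Recording duration.
#' @param k,window_s Threshold provenance.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(timestamps, electrode_id = NA_character_,
                        well_id = NA_character_, duration_s = NA_real_,
                        k = NA_real_, window_s = NA_real_) {
  timestamps <- as.numeric(timestamps)
  if (is.unsorted(timestamps)) stop("spike_train: timestamps must be sorted ascending")
  if (length(timestamps) && is.finite(duration_s) &&
      (timestamps[1] < 0 || timestamps[length(timestamps)] > duration_s))
    stop("spike_train: timestamps outside [0, duration_s]")
  structure(list(timestamps = timestamps, electrode_id = electrode_id,
                 well_id = well_id, duration_s = duration_s,
                 k = k, window_s = window_s),
            class = "spike_train")
}

#' Detect spikes by adaptive rolling-SD thresholding
#'
#' The per-sample threshold is `k` times the centered rolling SD of the
#' (band-pass filtered) trace. A spike is recorded for every contiguous
#' excursion of the signal beyond the threshold (per the polarity setting);
#' its timestamp is the sample of largest excursion amplitude within the
#' crossing (time of extremum, not first crossing). Excursions whose extremum
#' falls within `dead_time_s` of the previously kept spike are suppressed,
#' scanning in time order.
#'
#' Empty trains are valid and expected for silent electrodes.
#'
#' @param trace A [voltage_trace()]; should be filtered (a warning is issued
#'   otherwise, but detection proceeds).
#' @param tspec A [threshold_spec()].
#' @return A [spike_train()].
#' @export
detect_spikes <- function(trace, tspec = threshold_spec()) {
  stopifnot(inherits(trace, "voltage_trace"), inherits(tspec, "threshold_spec"))
  if (!trace$filtered)
    warning("detect_spikes: trace is not flagged as band-pass filtered; detecting anyway")
  x <- trace$samples
  n <- length(x)
  thr <- tspec$k * rolling_std(x, tspec$window_s, fs = trace$fs)
  exceed <- switch(tspec$polarity,
                   both = abs(x) > thr,
                   negative = x < -thr,
                   positive = x > thr)
  dur <- n / trace$fs
  if (!any(exceed)) {
    return(spike_train(numeric(0), trace$electrode_id, trace$well_id, dur,
                       k = tspec$k, window_s = tspec$window_s))
  }
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # extremum index within each excursion
  mag <- switch(tspec$polarity, both = abs(x), negative = -x, positive = x)
  idx <- vapply(runs, function(j) {
    s <- starts[j]; e <- ends[j]
    s + which.max(mag[s:e]) - 1L
  }, integer(1))
  ts <- (idx - 1L) / trace$fs
  # greedy dead-time suppression in time order
  if (tspec$dead_time_s > 0 && length(ts) > 1L) {
    keep <- logical(length(ts))
    last <- -Inf
    for (i in seq_along(ts)) {
      if (ts[i] - last >= tspec$dead_time_s) {
        keep[i] <- TRUE
        last <- ts[i]
      }
    }
    ts <- ts[keep]
  }
  spike_train(ts, trace$electrode_id, trace$well_id, dur,
              k = tspec$k, window_s = tspec$window_s)
}

#' Per-well spike-rate summary
#'
#' Per-electrode rate is spike count over duration. The well mean is the
#' arithmetic mean over all electrodes (silent ones included); an
#' "active-only" mean over electrodes firing at or above
#' `active_min_per_min` spikes/min is reported alongside, since instrument
#' vendors differ on this convention.
#'
#' @param trains List of [spike_train()]s from one well.
#' @param duration_s Recording duration in seconds (default 600).
#' @param active_min_per_min Activity cutoff, spikes per minute (default 5).
#' @return Object of class `well_activity`: per-electrode rates (Hz), well
#'   mean over all electrodes, active-only mean, active-electrode count.
#' @export
well_spike_rate <- function(trains, duration_s = 600, active_min_per_min = 5) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("well_spike_rate: 'duration_s' must be positive")
  counts <- vapply(trains, function(tr) length(tr$timestamps), numeric(1))
  rates <- counts / duration_s
  names(rates) <- vapply(trains, function(tr) as.character(tr$electrode_id), character(1))
  active <- rates >= active_min_per_min / 60
  structure(list(
    well_id = if (length(trains)) trains[[1]]$well_id else NA_character_,
    electrode_rates = rates,
    well_mean_rate = mean(rates),
    well_mean_rate_active = if (any(active)) mean(rates[active]) else 0,
    n_active = sum(active),
    duration_s = duration_s
  ), class = "well_activity")
}

#' @export
print.well_activity <- function(x, ...) {
  cat(sprintf("<well_activity> %s: mean %.4g Hz over %d electrodes (%d active, active-only mean %.4g Hz)\n",
              x$well_id, x$well_mean_rate, length(x$electrode_rates),
              x$n_active, x$well_mean_rate_active))
  invisible(x)
}

#' Export spike trains as a long-format raster table
#'
#' Writes `(well, electrode, timestamp_s)`, sorted electrode-major then by
#' time, as plain CSV. The round trip through [read_raster()] is lossless.
#'
#' @param trains List of [spike_train()]s.
#' @param path Output CSV path; if `NULL`, the data frame is returned only.
#' @return The table, invisibly when written.
#' @export
export_raster <- function(trains, path = NULL) {
  rows <- lapply(trains, function(tr) {
    if (length(tr$timestamps) == 0L) return(NULL)
    data.frame(well = tr$well_id, electrode = tr$electrode_id,
               timestamp_s = tr$timestamps, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(data.frame(well = character(0),
                                                electrode = character(0),
                                                timestamp_s = numeric(0)))))
  tab <- tab[order(tab$well, tab$electrode, tab$timestamp_s), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read a raster table back into spike trains
#'
#' @param path CSV written by [export_raster()].
#' @param duration_s Recording duration to stamp onto the trains.
#' @return List of [spike_train()]s, one per (well, electrode) present.
#' @export
read_raster <- function(path, duration_s = NA_real_) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "electrode", "timestamp_s")
  if (!all(need %in% names(tab)))
    stop("read_raster: missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  if (nrow(tab) == 0L) return(list())
  key <- interaction(tab$well, tab$electrode, drop = TRUE)
  lapply(split(tab, key), function(d) {
    spike_train(sort(d$timestamp_s), electrode_id = d$electrode[1],
                well_id = d$well[1], duration_s = duration_s)
  })
}
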