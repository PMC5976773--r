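#' Construct a fluorescence trace
#'
#' One ROI's calcium-indicator fluorescence time series, sampled at a fixed
#' interval (1 s for the 10-minute spinning-disc protocol this pipeline
#' targets). Time of sample `i` is `(i - 1) * dt` seconds.
#'
#' @param values Fluorescence values, arbitrary units; finite.
#' @param dt Sampling interval in seconds (default 1).
#' @param roi_id ROI label.
#' @param well_id,line,group Optional metadata carried through to summaries.
#' @param background_subtracted Provenance flag.
#' @return Object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, dt = 1, roi_id = NA_character_,
                               well_id = NA_character_, line = NA_character_,
                               group = NA_character_,
                               background_subtracted = FALSE) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("fluorescence_trace: values must be finite")
  if (!is.finite(dt) || dt <= 0) stop("fluorescence_trace: 'dt' must be positive")
  structure(list(values = values, dt = dt, roi_id = roi_id, well_id = well_id,
                 line = line, group = group,
                 background_subtracted = isTRUE(background_subtracted)),
            class = "fluorescence_trace")
}

#' Subtract image background from a trace
#'
#' @param trace A [fluorescence_trace()].
#' @param background Scalar, or a sequence the same length as the trace.
#' @return The trace with `background` removed and the provenance flag set.
#' @export
background_subtract <- function(trace, background) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (!all(is.finite(background))) stop("background_subtract: background must be finite")
  if (length(background) != 1L && length(background) != length(trace$values))
    stop("background_subtract: background length must be 1 or match the trace")
  trace$values <- trace$values - background
  trace$background_subtracted <- TRUE
  trace
}

#' Delimit candidate fluorescence peaks
#'
#' Candidates are strict local maxima of the trace; a plateau (run of equal
#' samples higher than both neighbours) collapses to a single candidate at
#' its midpoint (left of centre for even-length plateaus). From each peak the
#' routine walks outward while every next sample is strictly lower than the
#' previous one; the flank minimum is the last sample of that monotone
#' descent — the "furthest monotonically decreasing" minimum. An equal-value
#' step terminates the flank. Maxima at the trace boundary, which lack one of
#' the two flanks, are discarded.
#'
#' @param trace A [fluorescence_trace()] (or bare numeric vector). A warning
#'   is issued when the trace is not flagged background-subtracted.
#' @return Integer matrix with one row per candidate and columns
#'   `left_min`, `peak`, `right_min` (1-based indices); zero rows when no
#'   candidate exists.
#' @export
find_candidate_peaks <- function(trace) {
  if (inherits(trace, "fluorescence_trace")) {
    if (!trace$background_subtracted)
      warning("find_candidate_peaks: trace not flagged background-subtracted")
    y <- trace$values
  } else {
    y <- as.numeric(trace)
  }
  n <- length(y)
  empty <- matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("left_min", "peak", "right_min")))
  if (n < 3L) return(empty)
  out <- vector("list", 16L)
  k <- 0L
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L   # plateau extent
      if (j < n && y[j + 1L] < y[i]) {
        p <- i + (j - i) %/% 2L                         # plateau midpoint
        L <- i
        while (L > 1L && y[L - 1L] < y[L]) L <- L - 1L  # strict descent left
        R <- j
        while (R < n && y[R + 1L] < y[R]) R <- R + 1L   # strict descent right
        if (L < i && R > j) {                           # both flanks exist
          k <- k + 1L
          if (k > length(out)) out <- c(out, vector("list", length(out)))
          out[[k]] <- c(L, p, R)
        }
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (k == 0L) return(empty)
  m <- do.call(rbind, out[seq_len(k)])
  dimnames(m) <- list(NULL, c("left_min", "peak", "right_min"))
  m
}

#' Relevance area of one candidate peak
#'
#' Area of the triangle whose vertices are the peak and its two flank minima,
#' `(t_L, y_L), (t_P, y_P), (t_R, y_R)`, by the shoelace formula, with time
#' in seconds and fluorescence in trace units (so units are a.u. x s).
#' Invariant to adding a constant to all three y values and to time shifts;
#' collinear vertices give area 0. `method = "under_curve"` instead
#' integrates the trace between the two minima (trapezoid rule) above the
#' chord joining them — an alternative reading of an area "with vertices".
#'
#' @param trace A [fluorescence_trace()] or numeric vector.
#' @param triple Length-3 integer vector `(left_min, peak, right_min)` or one
#'   row of [find_candidate_peaks()] output.
#' @param dt Sampling interval when `trace` is a bare vector.
#' @param method `"triangle"` (default) or `"under_curve"`.
#' @return Non-negative area (a.u. x s).
#' @export
peak_relevance_area <- function(trace, triple, dt = NULL,
                                method = c("triangle", "under_curve")) {
  method <- match.arg(method)
  if (inherits(trace, "fluorescence_trace")) {
    y <- trace$values
    dt <- trace$dt
  } else {
    y <- as.numeric(trace)
    if (is.null(dt)) dt <- 1
  }
  triple <- as.integer(triple)
  if (length(triple) != 3L || triple[1] >= triple[2] || triple[2] >= triple[3] ||
      triple[1] < 1L || triple[3] > length(y))
    stop("peak_relevance_area: invalid (left, peak, right) triple")
  if (method == "triangle") {
    ts <- (triple - 1L) * dt
    ys <- y[triple]
    0.5 * abs((ts[2] - ts[1]) * (ys[3] - ys[1]) - (ts[3] - ts[1]) * (ys[2] - ys[1]))
  } else {
    idx <- triple[1]:triple[3]
    seg <- y[idx]
    chord <- seq(seg[1], seg[length(seg)], length.out = length(seg))
    d <- seg - chord
    sum((d[-1] + d[-length(d)]) / 2) * dt
  }
}

#' Call relevant peaks on one trace
#'
#' Scores every candidate peak with its relevance area and thresholds it.
#' The default rule is the literal one — area greater than one (population)
#' standard deviation above the mean of the signal itself:
#' `area > mean(values) + sd_multiplier * sd_pop(values)`. Two alternative
#' readings ship alongside: `"peak_population"` compares each area to the
#' mean + SD of the areas of the trace's candidate peaks, and `"sd_only"`
#' compares to `sd_multiplier * sd_pop(values)` with no mean term. The
#' literal rule compares an area (a.u. x s) with an amplitude statistic
#' (a.u.); the two coincide numerically at dt = 1 s, and a warning is issued
#' under that rule when dt differs from 1.
#'
#' @param trace A [fluorescence_trace()].
#' @param rule Threshold rule (see Details).
#' @param sd_multiplier Multiplier on the SD term (default 1).
#' @param area_method Passed to [peak_relevance_area()].
#' @return Data frame of peak calls: `peak_index`, `left_min_index`,
#'   `right_min_index`, `peak_time_s`, `amplitude` (peak value),
#'   `relevance_area`, `is_relevant`, plus the threshold used as an
#'   attribute `"threshold"`. Zero rows when there is no candidate.
#' @export
call_relevant_peaks <- function(trace,
                                rule = c("literal", "peak_population", "sd_only"),
                                sd_multiplier = 1,
                                area_method = c("triangle", "under_curve")) {
  rule <- match.arg(rule)
  area_method <- match.arg(area_method)
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (rule != "peak_population" && trace$dt != 1)
    warning("call_relevant_peaks: the '", rule,
            "' rule compares an area (a.u. x s) with an amplitude statistic; dt != 1 s")
  cand <- find_candidate_peaks(trace)
  calls <- data.frame(peak_index = integer(0), left_min_index = integer(0),
                      right_min_index = integer(0), peak_time_s = numeric(0),
                      amplitude = numeric(0), relevance_area = numeric(0),
                      is_relevant = logical(0))
  if (nrow(cand) == 0L) {
    attr(calls, "threshold") <- NA_real_
    return(calls)
  }
  areas <- apply(cand, 1L, function(tr) peak_relevance_area(trace, tr, method = area_method))
  y <- trace$values
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  threshold <- switch(rule,
    literal = mean(y) + sd_multiplier * sd_pop(y),
    peak_population = mean(areas) + sd_multiplier * sd_pop(areas),
    sd_only = sd_multiplier * sd_pop(y))
  calls <- data.frame(
    peak_index = cand[, "peak"],
    left_min_index = cand[, "left_min"],
    right_min_index = cand[, "right_min"],
    peak_time_s = (cand[, "peak"] - 1L) * trace$dt,
    amplitude = y[cand[, "peak"]],
    relevance_area = areas,
    is_relevant = areas > threshold
  )
  rownames(calls) <- NULL
  attr(calls, "threshold") <- threshold
  calls
}

#' Event frequency of one ROI
#'
#' Counts relevant peaks only; frequency in events per minute. A cell is
#' "active" when it shows at least one relevant event in the recording.
#'
#' @param peakcalls Output of [call_relevant_peaks()].
#' @param duration_s Recording duration, seconds.
#' @param roi_id Optional label (taken from calls if absent).
#' @return One-row data frame: `roi_id`, `n_relevant_events`,
#'   `freq_per_min`, `active`.
#' @export
event_frequency <- function(peakcalls, duration_s, roi_id = NA_character_) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("event_frequency: 'duration_s' must be positive")
  n <- sum(peakcalls$is_relevant)
  data.frame(roi_id = roi_id, n_relevant_events = n,
             freq_per_min = n / (duration_s / 60), active = n >= 1L,
             stringsAsFactors = FALSE)
}

#' Keep only active cells
#'
#' Restricts a table of per-ROI [event_frequency()] results to active cells
#' (>= 1 relevant event) and reports how many were excluded. Idempotent.
#'
#' @param results Data frame with an `active` column.
#' @return The active subset.
#' @export
active_cell_filter <- function(results) {
  stopifnot(is.data.frame(results), "active" %in% names(results))
  excluded <- sum(!results$active)
  if (excluded > 0)
    message(sprintf("active_cell_filter: excluded %d inactive cell(s) of %d",
                    excluded, nrow(results)))
  out <- results[results$active, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full calcium event-calling chain for one trace
#'
#' Background subtraction, candidate delimitation, relevance scoring and
#' event-frequency computation in one call.
#'
#' @inheritParams call_relevant_peaks
#' @param background Passed to [background_subtract()] (default 0).
#' @return List with elements `calls` (peak table) and `summary` (one-row
#'   [event_frequency()] result).
#' @export
ca_detect_trace <- function(trace, background = 0,
                            rule = c("literal", "peak_population", "sd_only"),
                            sd_multiplier = 1,
                            area_method = c("triangle", "under_curve")) {
  tr <- background_subtract(trace, background)
  calls <- call_relevant_peaks(tr, rule = rule, sd_multiplier = sd_multiplier,
                               area_method = area_method)
  dur <- length(tr$values) * tr$dt
  list(calls = calls,
       summary = event_frequency(calls, dur, roi_id = tr$roi_id))
}
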