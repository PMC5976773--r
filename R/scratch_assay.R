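#' Standardized scratch-counting region of interest
#'
#' The fixed rectangle inside which reinvading objects (cell bodies and
#' processes) are counted each day. Defaults are the standardized
#' 1.3 x 0.35 mm counting area.
#'
#' @param width_mm,height_mm Rectangle dimensions, mm.
#' @param x0_mm,y0_mm Lower-left corner in the imaging frame, mm.
#' @return Object of class `scratch_roi`.
#' @export
scratch_roi <- function(width_mm = 1.3, height_mm = 0.35, x0_mm = 0, y0_mm = 0) {
  if (!is.finite(width_mm) || width_mm <= 0 || !is.finite(height_mm) || height_mm <= 0)
    stop("scratch_roi: width and height must be positive")
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 x0_mm = x0_mm, y0_mm = y0_mm),
            class = "scratch_roi")
}

#' Count objects inside the scratch ROI
#'
#' Half-open rectangle on both axes: an object is counted when
#' `x in [x0, x0 + width)` and `y in [y0, y0 + height)`, so tiling ROIs never
#' double count. Records with non-finite coordinates are skipped with a
#' message.
#'
#' @param objects Data frame with columns `x_mm`, `y_mm` (one row per
#'   object), or a 2-column matrix.
#' @param roi A [scratch_roi()].
#' @return Integer count.
#' @export
count_in_roi <- function(objects, roi = scratch_roi()) {
  stopifnot(inherits(roi, "scratch_roi"))
  if (is.matrix(objects)) objects <- data.frame(x_mm = objects[, 1], y_mm = objects[, 2])
  if (nrow(objects) == 0L) return(0L)
  if (!all(c("x_mm", "y_mm") %in% names(objects)))
    stop("count_in_roi: 'objects' needs columns x_mm, y_mm")
  ok <- is.finite(objects$x_mm) & is.finite(objects$y_mm)
  if (any(!ok))
    message(sprintf("count_in_roi: skipped %d record(s) with non-finite coordinates", sum(!ok)))
  x <- objects$x_mm[ok]; y <- objects$y_mm[ok]
  sum(x >= roi$x0_mm & x < roi$x0_mm + roi$width_mm &
      y >= roi$y0_mm & y < roi$y0_mm + roi$height_mm)
}

#' Reinvasion time course for one well
#'
#' Returns the raw daily counts, counts per mm-squared of ROI area
#' (density), and counts normalized to a reference day's value (the last
#' imaging day by default; set `ref_day` to the end of the common
#' pre-divergence window to express later counts as fold change over it).
#' No smoothing is applied.
#'
#' @param series Data frame with columns `day`, `count` (e.g. a
#'   [simulate_scratch_series()] result); at least 2 days.
#' @param roi A [scratch_roi()] giving the counting area.
#' @param ref_day Day whose count normalizes the curve (default: last day).
#' @return Data frame: `day`, `count`, `density_per_mm2`, `normalized`.
#' @export
reinvasion_timecourse <- function(series, roi = scratch_roi(), ref_day = NULL) {
  stopifnot(is.data.frame(series), all(c("day", "count") %in% names(series)))
  if (anyDuplicated(series$day)) stop("reinvasion_timecourse: duplicate days")
  series <- series[order(series$day), , drop = FALSE]
  if (nrow(series) < 2L) stop("reinvasion_timecourse: need at least 2 days")
  if (any(series$count < 0)) stop("reinvasion_timecourse: counts must be >= 0")
  area <- roi$width_mm * roi$height_mm
  if (is.null(ref_day)) ref_day <- max(series$day)
  ref <- series$count[series$day == ref_day]
  if (length(ref) != 1L) stop("reinvasion_timecourse: ref_day not present in series")
  data.frame(day = series$day, count = series$count,
             density_per_mm2 = series$count / area,
             normalized = if (ref > 0) series$count / ref else NA_real_)
}

#' Recovery rate of one well
#'
#' Least-squares slope of count versus day (objects/day), with its standard
#' error and a confidence interval — the "rate of repopulation" summary of a
#' scratch series.
#'
#' @param series Data frame with `day`, `count`; at least 3 distinct days.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List: `slope`, `se`, `ci` (length-2), `df`.
#' @export
recovery_rate <- function(series, conf_level = 0.95) {
  stopifnot(is.data.frame(series), all(c("day", "count") %in% names(series)))
  if (length(unique(series$day)) < 3L)
    stop("recovery_rate: need at least 3 distinct days")
  if (stats::var(series$day) == 0)
    stop("recovery_rate: degenerate series (all days equal)")
  fit <- stats::lm(count ~ day, data = series)
  # suppress the "perfect fit" warning: exact lines are legitimate inputs
  est <- suppressWarnings(summary(fit)$coefficients["day", ])
  ci <- suppressWarnings(stats::confint(fit, "day", level = conf_level))
  list(slope = unname(est["Estimate"]), se = unname(est["Std. Error"]),
       ci = as.numeric(ci), df = fit$df.residual)
}
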