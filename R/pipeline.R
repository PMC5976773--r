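#' Detect spikes across one simulated well, streaming electrode by electrode
#'
#' Filters and thresholds each electrode trace in turn, keeping only spike
#' times, so a full-length 64-electrode well never has to be held in memory
#' after generation.
#'
#' @param well A [simulate_mea_well()] result with traces.
#' @param fspec A [filter_spec()].
#' @param tspec A [threshold_spec()].
#' @return List of [spike_train()]s.
#' @export
mea_detect_well <- function(well, fspec = filter_spec(), tspec = threshold_spec()) {
  if (is.null(well$traces)) stop("mea_detect_well: well has no traces (count fidelity?)")
  lapply(well$traces, function(tr) detect_spikes(bandpass_filter(tr, fspec), tspec))
}

# ---- configuration ---------------------------------------------------------

config_schema <- function() {
  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  pos <- function(x) num(x) && x > 0
  list(
    seed = function(x) num(x) && x == round(x),
    out = is.character,
    simulate = list(
      fidelity = function(x) is.character(x) && x %in% c("counts", "traces"),
      params = function(x) is.list(x) &&
        all(names(x) %in% names(formals(synth_params)))
    ),
    mea = list(
      filter = list(low_hz = pos, high_hz = pos,
                    order = function(x) isTRUE(x == 1)),
      threshold = list(k = pos, window_s = pos,
                       dead_time_s = function(x) num(x) && x >= 0,
                       polarity = function(x)
                         is.character(x) && x %in% c("both", "negative", "positive")),
      active_rate_min_per_min = function(x) num(x) && x >= 0
    ),
    ca = list(
      rule = function(x) is.character(x) &&
        x %in% c("literal", "peak_population", "sd_only"),
      sd_multiplier = pos,
      background = num,
      area_method = function(x) is.character(x) &&
        x %in% c("triangle", "under_curve")
    ),
    scratch = list(roi = list(width_mm = pos, height_mm = pos)),
    stats = list(
      unit = function(x) is.character(x) && x %in% c("well", "cell"),
      alpha = function(x) num(x) && x > 0 && x < 1,
      gg_correction = function(x) is.logical(x) && length(x) == 1L
    )
  )
}

#' Default pipeline configuration
#'
#' @return Nested named list; see [validate_config()] for the schema.
#' @export
default_config <- function() {
  list(
    seed = 1,
    simulate = list(fidelity = "counts", params = list()),
    mea = list(filter = list(low_hz = 200, high_hz = 2500, order = 1),
               threshold = list(k = 5.25, window_s = 0.1, dead_time_s = 0.001,
                                polarity = "both"),
               active_rate_min_per_min = 5),
    ca = list(rule = "literal", sd_multiplier = 1, background = 0,
              area_method = "triangle"),
    scratch = list(roi = list(width_mm = 1.3, height_mm = 0.35)),
    stats = list(unit = "well", alpha = 0.05, gg_correction = FALSE)
  )
}

check_against <- function(cfg, schema, path = "") {
  if (!is.list(cfg)) stop("config: '", path, "' must be a mapping")
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("config: unknown key(s) under '", if (nzchar(path)) path else "<root>",
         "': ", paste(unknown, collapse = ", "))
  for (nm in names(cfg)) {
    sub <- schema[[nm]]
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (is.list(sub)) {
      check_against(cfg[[nm]], sub, here)
    } else if (!isTRUE(sub(cfg[[nm]]))) {
      stop("config: invalid value for '", here, "': ",
           paste(utils::capture.output(utils::str(cfg[[nm]])), collapse = " "))
    }
  }
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' Checks the nested configuration against the pipeline schema before any
#' computation or I/O: unknown keys are rejected, and every known value must
#' satisfy its type/range predicate (e.g. `mea.threshold.k > 0`).
#'
#' @param config Nested named list (e.g. parsed from YAML).
#' @return The config merged over [default_config()] (validated), invisibly
#'   usable downstream.
#' @export
validate_config <- function(config) {
  check_against(config, config_schema())
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_cfg(default_config(), config)
  # cross-field checks that need merged values
  if (cfg$mea$filter$low_hz >= cfg$mea$filter$high_hz)
    stop("config: mea.filter.low_hz must be below high_hz")
  cfg
}

#' Read and validate a YAML configuration file
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

# ---- input validation ------------------------------------------------------

#' Validate pipeline input files
#'
#' Checks each file for readability and the expected column layout without
#' mutating anything. Unreadable or malformed files yield a failure entry,
#' never an error.
#'
#' @param paths Named list with any of: `design` (one CSV), `mea` (vector of
#'   well CSVs with `time_s, e00...`), `mea_counts` (one CSV:
#'   `well, electrode, n_spikes`), `ca` (vector of CSVs with
#'   `time_s, roi_*`), `scratch` (one CSV: `well, day, count`).
#' @return Data frame: `file`, `kind`, `ok`, `reason`.
#' @export
validate_inputs <- function(paths) {
  res <- list()
  add <- function(file, kind, ok, reason = "") {
    res[[length(res) + 1L]] <<- data.frame(file = file, kind = kind, ok = ok,
                                           reason = reason, stringsAsFactors = FALSE)
  }
  try_read <- function(f) tryCatch(suppressWarnings(utils::read.csv(f, nrows = 5)),
                                   error = function(e) e)
  check_cols <- function(f, kind, need, extra_check = NULL) {
    h <- try_read(f)
    if (inherits(h, "error")) return(add(f, kind, FALSE, conditionMessage(h)))
    miss <- setdiff(need, names(h))
    if (length(miss)) return(add(f, kind, FALSE,
                                 paste("missing column(s):", paste(miss, collapse = ", "))))
    if (!is.null(extra_check)) {
      r <- extra_check(h)
      if (!isTRUE(r)) return(add(f, kind, FALSE, r))
    }
    add(f, kind, TRUE)
  }
  if (!is.null(paths$design)) {
    check_cols(paths$design, "design", c("well", "line", "group", "replicate"),
               function(h) {
                 bad <- setdiff(unique(h$group), c("case", "control"))
                 if (length(bad)) paste("unknown group label(s):",
                                        paste(bad, collapse = ", ")) else TRUE
               })
  }
  for (f in paths$mea) {
    check_cols(f, "mea", "time_s", function(h) {
      ecols <- grep("^e[0-9]+$", names(h), value = TRUE)
      if (length(ecols) == 0L) "no electrode columns (e00...)" else TRUE
    })
  }
  if (!is.null(paths$mea_counts))
    check_cols(paths$mea_counts, "mea_counts", c("well", "electrode", "n_spikes"))
  for (f in paths$ca) {
    check_cols(f, "ca", "time_s", function(h) {
      if (!any(grepl("^roi", names(h)))) "no ROI columns (roi_0...)" else TRUE
    })
  }
  if (!is.null(paths$scratch))
    check_cols(paths$scratch, "scratch", c("well", "day", "count"))
  if (length(res) == 0L)
    return(data.frame(file = character(0), kind = character(0),
                      ok = logical(0), reason = character(0)))
  do.call(rbind, res)
}

# ---- cohort-level summaries ------------------------------------------------

#' Per-well MEA rate table for a cohort
#'
#' At count fidelity the per-electrode rates come from the ground-truth
#' spike counts (what perfect detection would return); at trace fidelity the
#' full filter + detect chain is run.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param cfg Validated config (for filter/threshold settings).
#' @return Data frame: `well`, `line`, `group`, `replicate`,
#'   `mean_rate_hz`, `mean_rate_active_hz`, `n_active`.
#' @export
cohort_mea_rates <- function(cohort, cfg = validate_config(list())) {
  fspec <- filter_spec(cfg$mea$filter$low_hz, cfg$mea$filter$high_hz)
  tspec <- threshold_spec(cfg$mea$threshold$k, cfg$mea$threshold$window_s,
                          cfg$mea$threshold$dead_time_s, cfg$mea$threshold$polarity)
  amin <- cfg$mea$active_rate_min_per_min
  rows <- lapply(seq_len(nrow(cohort$design)), function(i) {
    w <- cohort$design$well[i]
    m <- cohort$mea[[w]]
    dur <- cohort$params$duration_s
    if (identical(cohort$fidelity, "traces")) {
      trains <- mea_detect_well(m, fspec, tspec)
    } else {
      trains <- lapply(names(m$truth$spike_times), function(e)
        spike_train(m$truth$spike_times[[e]], electrode_id = e, well_id = w,
                    duration_s = dur))
    }
    ws <- well_spike_rate(trains, duration_s = dur, active_min_per_min = amin)
    data.frame(well = w, line = cohort$design$line[i],
               group = cohort$design$group[i],
               replicate = cohort$design$replicate[i],
               mean_rate_hz = ws$well_mean_rate,
               mean_rate_active_hz = ws$well_mean_rate_active,
               n_active = ws$n_active, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-well calcium event-frequency table for a cohort
#'
#' Runs the full event-calling chain on every simulated ROI, applies the
#' active-cell filter, and summarises per well (mean frequency over active
#' cells) or per cell.
#'
#' @inheritParams cohort_mea_rates
#' @return Data frame with one row per well (`unit = "well"`, default) or
#'   per active cell (`unit = "cell"`): labels plus `freq_per_min`,
#'   `n_active_cells`.
#' @export
cohort_ca_frequencies <- function(cohort, cfg = validate_config(list())) {
  unit <- cfg$stats$unit
  rows <- lapply(seq_len(nrow(cohort$design)), function(i) {
    w <- cohort$design$well[i]
    cells <- cohort$calcium[[w]]
    per_cell <- do.call(rbind, lapply(cells, function(cl) {
      det <- ca_detect_trace(cl$trace, background = cfg$ca$background,
                             rule = cfg$ca$rule,
                             sd_multiplier = cfg$ca$sd_multiplier,
                             area_method = cfg$ca$area_method)
      det$summary
    }))
    act <- suppressMessages(active_cell_filter(per_cell))
    base <- data.frame(well = w, line = cohort$design$line[i],
                       group = cohort$design$group[i],
                       replicate = cohort$design$replicate[i],
                       stringsAsFactors = FALSE)
    if (unit == "well") {
      cbind(base, data.frame(
        freq_per_min = if (nrow(act)) mean(act$freq_per_min) else 0,
        n_active_cells = nrow(act)))
    } else if (nrow(act)) {
      cbind(base[rep(1L, nrow(act)), , drop = FALSE],
            act[, c("roi_id", "freq_per_min")],
            n_active_cells = nrow(act))
    } else {
      NULL
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scratch count table for a cohort
#'
#' @inheritParams cohort_mea_rates
#' @return Long data frame: `well`, `group`, `line`, `replicate`, `day`,
#'   `count`, `density_per_mm2`, `normalized`.
#' @export
cohort_scratch_table <- function(cohort, cfg = validate_config(list())) {
  roi <- scratch_roi(cfg$scratch$roi$width_mm, cfg$scratch$roi$height_mm)
  rows <- lapply(seq_len(nrow(cohort$design)), function(i) {
    w <- cohort$design$well[i]
    s <- cohort$scratch[[w]]
    tc <- reinvasion_timecourse(s, roi = roi)
    data.frame(well = w, group = cohort$design$group[i],
               line = cohort$design$line[i],
               replicate = cohort$design$replicate[i],
               tc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- end-to-end run --------------------------------------------------------

#' Run the full simulate -> detect -> summarize -> test pipeline
#'
#' Simulates a cohort from the validated configuration, runs all three assay
#' arms, and computes the group statistics: case/control one-way ANOVA with
#' Tukey HSD for the MEA and calcium endpoints (plus an all-lines ANOVA with
#' line-vs-line Tukey contrasts), and the mixed repeated-measures ANOVA for
#' the scratch time course. Deterministic given the config (which includes
#' the seed). When `out_dir` is given, every intermediate table is written as
#' CSV together with a plain-text report; each table carries the config hash
#' in a comment-free sidecar (`provenance.json`).
#'
#' @param config Config list (validated via [validate_config()]), or a path
#'   to a YAML file.
#' @param out_dir Optional output directory.
#' @param force Overwrite non-empty `out_dir`.
#' @return Object of class `cohort_report`: `mea`, `calcium`, `scratch`
#'   tables; `stats` (per-assay test results and group summaries);
#'   `provenance` (config hash, seed, package version).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, force = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  if (!is.null(out_dir) && dir.exists(out_dir) &&
      length(dir(out_dir, all.files = TRUE, no.. = TRUE)) > 0 && !force)
    stop("run_pipeline: output path '", out_dir, "' exists; use force = TRUE")
  sp <- do.call(synth_params, c(list(seed = as.integer(cfg$seed)),
                                cfg$simulate$params))
  cohort <- simulate_cohort(sp, fidelity = cfg$simulate$fidelity)
  mea_tab <- cohort_mea_rates(cohort, cfg)
  ca_tab <- cohort_ca_frequencies(cohort, cfg)
  scr_tab <- cohort_scratch_table(cohort, cfg)
  two_group <- function(tab, col) {
    anova_tukey(grouped_values(tab[[col]], tab$group))
  }
  by_line <- function(tab, col) {
    anova_tukey(grouped_values(tab[[col]], tab$line))
  }
  rm_in <- data.frame(value = scr_tab$count, subject = scr_tab$well,
                      group = scr_tab$group, time = scr_tab$day)
  stats_out <- list(
    mea = list(group_anova = two_group(mea_tab, "mean_rate_hz"),
               line_anova = by_line(mea_tab, "mean_rate_hz"),
               summary = group_summary(data.frame(value = mea_tab$mean_rate_hz,
                                                  group = mea_tab$group))),
    calcium = list(group_anova = two_group(ca_tab, "freq_per_min"),
                   line_anova = by_line(ca_tab, "freq_per_min"),
                   summary = group_summary(data.frame(value = ca_tab$freq_per_min,
                                                      group = ca_tab$group))),
    scratch = list(rm_anova = rm_anova(rm_in),
                   summary_by_day = do.call(rbind, lapply(
                     split(scr_tab, scr_tab$day), function(d)
                       cbind(day = d$day[1],
                             group_summary(data.frame(value = d$count,
                                                      group = d$group))))))
  )
  prov <- list(config_hash = digest::digest(cfg), seed = cfg$seed,
               package_version = as.character(utils::packageVersion("neuroassay")))
  report <- structure(list(design = cohort$design, mea = mea_tab,
                           calcium = ca_tab, scratch = scr_tab,
                           stats = stats_out, provenance = prov,
                           config = cfg),
                      class = "cohort_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$design, file.path(out_dir, "design.csv"), row.names = FALSE)
  utils::write.csv(report$mea, file.path(out_dir, "mea_well_rates.csv"), row.names = FALSE)
  utils::write.csv(report$calcium, file.path(out_dir, "ca_frequencies.csv"), row.names = FALSE)
  utils::write.csv(report$scratch, file.path(out_dir, "scratch_timecourse.csv"), row.names = FALSE)
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(out_dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("== Cohort report ==\n")
  cat(sprintf("seed %s, config %s, neuroassay %s\n\n", x$provenance$seed,
              x$provenance$config_hash, x$provenance$package_version))
  cat("-- MEA well spike rate (Hz) --\n")
  print(x$stats$mea$summary, digits = 4)
  print(x$stats$mea$group_anova)
  cat("\n-- Calcium event frequency (events/min) --\n")
  print(x$stats$calcium$summary, digits = 4)
  print(x$stats$calcium$group_anova)
  cat("\n-- Scratch reinvasion --\n")
  print(x$stats$scratch$rm_anova)
  invisible(x)
}
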