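#' Validate grouped observations
#'
#' @param value Numeric observations.
#' @param group Group label per observation (e.g. iPSC line, or case/control).
#' @param line,replicate Optional extra labels carried along.
#' @return Data frame of class `grouped_values`.
#' @export
grouped_values <- function(value, group, line = NULL, replicate = NULL) {
  if (!all(is.finite(value))) stop("grouped_values: values must be finite")
  group <- as.character(group)
  if (length(group) != length(value)) stop("grouped_values: length mismatch")
  d <- data.frame(value = as.numeric(value), group = group,
                  stringsAsFactors = FALSE)
  if (!is.null(line)) d$line <- as.character(line)
  if (!is.null(replicate)) d$replicate <- replicate
  class(d) <- c("grouped_values", "data.frame")
  d
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' F test across groups followed by all-pairs Tukey honest significant
#' differences on the studentized-range distribution; unbalanced groups use
#' the Tukey-Kramer form (the base-R [stats::TukeyHSD()] behaviour).
#'
#' @param data A [grouped_values()] data frame, or any data frame with
#'   `value` and `group` columns. At least 2 groups and 2 observations per
#'   group.
#' @param conf_level Confidence level for the Tukey intervals.
#' @return Object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, and `pairwise` (data frame: `group_i`, `group_j`, `diff`, `lwr`,
#'   `upr`, `p_adj`).
#' @export
anova_tukey <- function(data, conf_level = 0.95) {
  stopifnot(is.data.frame(data), all(c("value", "group") %in% names(data)))
  tab <- table(data$group)
  if (length(tab) < 2L) stop("anova_tukey: need at least 2 groups")
  if (any(tab < 2L))
    stop("anova_tukey: every group needs >= 2 observations (offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  d <- data.frame(value = data$value, group = factor(data$group))
  fit <- stats::aov(value ~ group, data = d)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  structure(list(
    F = an[["F value"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2],
    p = an[["Pr(>F)"]][1],
    pairwise = data.frame(group_i = pairs[, 1], group_j = pairs[, 2],
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE)
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Mixed-design (split-plot) repeated-measures ANOVA
#'
#' Between-subject factor `group`, within-subject factor `time`
#' (e.g. imaging day), each subject (well) observed at every time point.
#' Reports the group effect (tested against subjects-within-groups), the
#' time effect and the group x time interaction (tested against the
#' subject x time residual). Sphericity is assumed for the default p values;
#' the Greenhouse-Geisser epsilon and GG-corrected p values are reported
#' alongside for transparency.
#'
#' @param data Data frame with columns `value`, `subject`, `group`, `time`.
#'   The design must be complete: every subject at every time, one
#'   observation per cell.
#' @return Object of class `rm_anova_result`: data frame `table` with rows
#'   `group`, `time`, `group:time` (columns `F`, `df1`, `df2`, `p`,
#'   `p_gg`), plus `gg_epsilon`.
#' @export
rm_anova <- function(data) {
  need <- c("value", "subject", "group", "time")
  stopifnot(is.data.frame(data))
  if (!all(need %in% names(data)))
    stop("rm_anova: missing columns: ", paste(setdiff(need, names(data)), collapse = ", "))
  d <- data.frame(value = as.numeric(data$value),
                  subject = factor(data$subject),
                  group = factor(data$group),
                  time = factor(data$time))
  # complete-design check
  cells <- table(d$subject, d$time)
  if (any(cells != 1L)) {
    bad <- which(cells != 1L, arr.ind = TRUE)
    msg <- apply(bad, 1L, function(i)
      sprintf("(%s, %s): %d", rownames(cells)[i[1]], colnames(cells)[i[2]],
              cells[i[1], i[2]]))
    stop("rm_anova: design not complete; offending (subject, time) cells: ",
         paste(utils::head(msg, 10L), collapse = "; "))
  }
  grp_of <- tapply(as.character(d$group), d$subject, function(g) g[1])
  if (any(tapply(as.character(d$group), d$subject, function(g) length(unique(g))) != 1L))
    stop("rm_anova: a subject appears in more than one group")
  fit <- stats::aov(value ~ group * time + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  get_row <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"], ss = tab[i, "Sum Sq"])
  }
  rows <- rbind(group = get_row(between, "group"),
                time = get_row(within, "time"),
                `group:time` = get_row(within, "group:time"))
  tabl <- as.data.frame(rows)
  # a term whose sum of squares is numerically zero is "no effect": report
  # F = 0, p = 1 rather than the 0/0 (or noise/noise) ratio
  scale_ss <- sum(d$value^2) + 1
  degenerate <- !is.finite(tabl$F) | tabl$ss <= 1e-10 * scale_ss
  tabl$F[degenerate] <- 0
  tabl$p[degenerate] <- 1
  tabl$ss <- NULL
  # Greenhouse-Geisser epsilon from the pooled within-group covariance of
  # the subject x time response matrix
  wide <- tapply(d$value, list(d$subject, d$time), mean)  # one obs per cell
  groups <- grp_of[rownames(wide)]
  centred <- wide
  for (g in unique(groups)) {
    rows_g <- groups == g
    centred[rows_g, ] <- sweep(wide[rows_g, , drop = FALSE], 2,
                               colMeans(wide[rows_g, , drop = FALSE]))
  }
  n_t <- ncol(wide)
  S <- crossprod(centred) / (nrow(wide) - length(unique(groups)))
  C <- diag(n_t) - 1 / n_t
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / ((n_t - 1) * sum(Sc * Sc))
  eps <- min(1, max(eps, 1 / (n_t - 1)))
  tabl$p_gg <- tabl$p
  for (nm in c("time", "group:time")) {
    tabl[nm, "p_gg"] <- stats::pf(tabl[nm, "F"], eps * tabl[nm, "df1"],
                                  eps * tabl[nm, "df2"], lower.tail = FALSE)
  }
  structure(list(table = tabl, gg_epsilon = eps), class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (between: group, within: time)\n")
  print(round(x$table, 5))
  cat(sprintf("Greenhouse-Geisser epsilon = %.4f (p_gg applies to time terms)\n",
              x$gg_epsilon))
  invisible(x)
}

#' Per-group mean and standard error
#'
#' SEM uses the sample SD (n - 1 denominator). Groups with a single
#' observation get SEM 0 by convention and are flagged.
#'
#' @param data Data frame with `value` and `group` columns.
#' @return Data frame: `group`, `n`, `mean`, `sem`, `single_obs` flag.
#' @export
group_summary <- function(data) {
  stopifnot(is.data.frame(data), all(c("value", "group") %in% names(data)))
  out <- do.call(rbind, lapply(split(data$value, data$group), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0,
               single_obs = length(v) == 1L)
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out$group <- as.character(out$group)
  if (any(out$single_obs))
    message("group_summary: SEM set to 0 for single-observation group(s): ",
            paste(out$group[out$single_obs], collapse = ", "))
  out
}
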