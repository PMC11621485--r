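# End-to-end pipeline: trial summary table in, effect table out, with the
# pilot-study conventions (age fill-ins, sex-ratio defaults, mode
# inference) applied and logged.

DAYS_PER_MONTH <- 30.4375

#' Read a long-format trial summary table
#'
#' One row per trial x arm x timepoint. Required columns: `trial`,
#' `arm`, `role`, `timepoint`, `n`, `metric`, `value`; optional:
#' `scheduled_age_days`, `mean_age_days` (at least one age must be
#' present per row), `scheduled_age_months` / `mean_age_months`
#' (converted at 30.4375 d/mo and logged), `ci_low`, `ci_high`,
#' `proportion_female`, `mode`. Comma- or tab-delimited with a header.
#'
#' @param path path to the delimited file.
#' @return A data frame in the pipeline schema (ages in days; missing
#'   optional columns added as `NA`), with attribute `unit_log`
#'   recording any month-to-day conversions.
#' @export
read_trial_summary <- function(path) {
  if (!file.exists(path)) stop("trial summary file not found: ", path, call. = FALSE)
  df <- read_delimited(path)
  required <- c("trial", "arm", "role", "timepoint", "n", "metric", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("trial summary lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unit_log <- character(0)
  for (col in c("scheduled_age", "mean_age")) {
    mo <- paste0(col, "_months"); dy <- paste0(col, "_days")
    if (mo %in% names(df)) {
      conv <- df[[mo]] * DAYS_PER_MONTH
      if (!dy %in% names(df)) df[[dy]] <- NA_real_
      fill <- is.na(df[[dy]]) & !is.na(conv)
      df[[dy]][fill] <- conv[fill]
      unit_log <- c(unit_log, sprintf(
        "converted %s from months to days (30.4375 d/mo) for %d row(s)",
        col, sum(fill)))
      df[[mo]] <- NULL
    }
  }
  for (col in c("scheduled_age_days", "mean_age_days", "ci_low", "ci_high",
                "proportion_female")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (!"mode" %in% names(df)) df$mode <- "infer"
  df$mode[is.na(df$mode)] <- "infer"
  bad <- which(is.na(df$scheduled_age_days) & is.na(df$mean_age_days))
  if (length(bad) > 0L) {
    stop("row(s) ", paste(bad, collapse = ", "),
         ": neither scheduled_age_days nor mean_age_days present", call. = FALSE)
  }
  ok_ci <- is.na(df$ci_low) | is.na(df$ci_high) |
    (df$ci_low <= df$value & df$value <= df$ci_high)
  if (!all(ok_ci)) {
    stop("row(s) ", paste(which(!ok_ci), collapse = ", "),
         ": CI does not bracket the value", call. = FALSE)
  }
  attr(df, "unit_log") <- unit_log
  df
}

#' Apply the pilot-study conventions to a trial summary table
#'
#' Fills each gap the way the pilot analysis does, and logs every
#' substitution exactly once per record: a missing mean age is assumed
#' to equal the scheduled timing of measurement; a missing sex ratio is
#' assumed equal (0.5); a mode of `"infer"` is resolved from the mean
#' age by the two-year rule ([resolve_mode()]).
#'
#' @param records a data frame in the [read_trial_summary()] schema.
#' @return A list with `records` (conventions applied) and `log`
#'   (character vector, one entry per substitution).
#' @export
apply_pilot_conventions <- function(records) {
  log <- character(0)
  note <- function(i, what) sprintf("row %d (%s/%s/%s): %s", i,
                                    records$trial[i], records$arm[i],
                                    records$timepoint[i], what)
  for (i in seq_len(nrow(records))) {
    if (is.na(records$mean_age_days[i])) {
      if (is.na(records$scheduled_age_days[i])) {
        stop("row ", i, ": both mean and scheduled age missing", call. = FALSE)
      }
      records$mean_age_days[i] <- records$scheduled_age_days[i]
      log <- c(log, note(i, sprintf("mean age assumed equal to scheduled timing (%g d)",
                                    records$scheduled_age_days[i])))
    }
    if (is.na(records$proportion_female[i])) {
      records$proportion_female[i] <- 0.5
      log <- c(log, note(i, "equal sex ratio assumed (proportion_female = 0.5)"))
    }
    if (records$mode[i] == "infer") {
      records$mode[i] <- resolve_mode(records$mean_age_days[i])
      log <- c(log, note(i, sprintf("mode inferred from mean age: %s",
                                    records$mode[i])))
    }
  }
  list(records = records, log = log)
}

#' Run the full re-expression pipeline
#'
#' Reads (or accepts) a growth reference and a trial summary table,
#' applies the pilot conventions, and emits the effect table: per trial
#' and contrast, the native-metric MD, height-age MD, MD of changes in
#' height-age, and PMB with 95% CIs, with `NA` cells carrying the reason
#' they could not be derived (the run continues past per-cell failures).
#' Deterministic: identical inputs produce identical output tables.
#'
#' @param trials a data frame in the [read_trial_summary()] schema, or a
#'   path to such a file.
#' @param ref a two-sex [growth_reference()], or a path passed to
#'   [load_reference()].
#' @param dialect reference dialect when `ref` is a path.
#' @param corr baseline-endline correlation (see [change_in_height_age()]).
#' @param interpolate use interpolated (fractional-day) lookups.
#' @param out optional path; when given, the effect table is written
#'   there as comma-delimited text.
#' @param verbose print the convention log to standard error.
#' @return A list with `results` (the effect table) and `log` (all
#'   conventions and unit conversions applied).
#' @export
run_reexpression <- function(trials, ref, dialect = "who_lenanthro",
                             corr = 0, interpolate = FALSE, out = NULL,
                             verbose = FALSE) {
  if (is.character(trials)) trials <- read_trial_summary(trials)
  if (is.character(ref)) ref <- load_reference(ref, dialect)
  log <- attr(trials, "unit_log")
  conv <- apply_pilot_conventions(trials)
  log <- c(log, conv$log)
  results <- effect_table(conv$records, ref, corr = corr,
                          interpolate = interpolate)
  if (verbose && length(log) > 0L) {
    message(paste(log, collapse = "\n"))
  }
  if (!is.null(out)) {
    utils::write.csv(results, out, row.names = FALSE)
  }
  list(results = results, log = log)
}

#' Height-age-for-age plot
#'
#' Plots each arm's derived height-age against chronologic age, with the
#' optimal-growth identity line (height-age advancing one day per day of
#' chronologic age, slope 1) as the benchmark. Arms tracking the
#' standard's median sit on the line; faltering arms fall below it, and
#' an effective intervention shows a segment climbing parallel to it.
#'
#' @param arm_points data frame with columns `arm`, `age_days`
#'   (chronologic age) and `height_age_days` (derived height-age), one
#'   row per arm x timepoint.
#' @param out optional file path; when given the plot is saved there
#'   (format from the extension, e.g. `.png` or `.pdf`).
#' @return The ggplot object, invisibly when saved.
#' @export
plot_height_age_for_age <- function(arm_points, out = NULL) {
  stopifnot(is.data.frame(arm_points))
  if (nrow(arm_points) == 0L) stop("no points to plot", call. = FALSE)
  needed <- c("arm", "age_days", "height_age_days")
  if (!all(needed %in% names(arm_points))) {
    stop("arm_points needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  p <- ggplot2::ggplot(arm_points,
                       ggplot2::aes(x = .data$age_days, y = .data$height_age_days,
                                    colour = .data$arm, group = .data$arm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Chronologic age (d)", y = "Height-age (d)",
                  colour = "Arm",
                  caption = "dashed line: optimal growth (slope = 1)") +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 6, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Write a growth reference or record table as delimited text
#'
#' Round-trips the formats the package reads, so synthetic fixtures
#' double as format documentation.
#'
#' @param x a [growth_reference()] or data frame.
#' @param path output path.
#' @param sep field separator (comma default).
#' @return `path`, invisibly.
#' @export
write_delimited <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
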