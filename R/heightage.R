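# Height-age derivation from group summaries or individual records,
# plus the z-score machinery and distribution moments.

# 95% normal quantile used for every CI in the package
Z95 <- 1.959964

#' Group-level stature summary
#'
#' Bundles the quantities needed to derive a group height-age: the mean
#' (raw stature in cm or a z-score), its 95% CI if reported, the group
#' size, the mean age at measurement, the sex ratio, and the measurement
#' mode (`"infer"` applies the two-year rule via [resolve_mode()]).
#'
#' @param metric `"stature"` (cm) or `"zscore"`.
#' @param value group mean on the `metric` scale.
#' @param ci_low,ci_high reported 95% CI bounds (optional, `NA` if absent).
#' @param n group size (optional).
#' @param mean_age_days mean chronologic age at measurement, days.
#' @param proportion_female fraction of females, used to sex-weight the
#'   reference; defaults to an equal ratio.
#' @param mode `"length"`, `"height"`, or `"infer"`.
#' @return An object of class `summary_stature`.
#' @export
summary_stature <- function(metric = c("stature", "zscore"), value,
                            ci_low = NA_real_, ci_high = NA_real_,
                            n = NA_integer_, mean_age_days,
                            proportion_female = 0.5,
                            mode = c("infer", "length", "height")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  stopifnot(is.finite(value), is.finite(mean_age_days), mean_age_days >= 0)
  if (!is.na(ci_low) && !is.na(ci_high) && !(ci_low <= value && value <= ci_high)) {
    stop("CI (", ci_low, ", ", ci_high, ") must bracket the mean ", value,
         call. = FALSE)
  }
  structure(list(metric = metric, value = value, ci_low = ci_low,
                 ci_high = ci_high, n = n, mean_age_days = mean_age_days,
                 proportion_female = proportion_female, mode = mode),
            class = "summary_stature")
}

height_age_estimate <- function(point, se = NA_real_, ci_low = NA_real_,
                                ci_high = NA_real_, method, provenance = "") {
  structure(list(point = point, se = se, ci_low = ci_low, ci_high = ci_high,
                 method = method, reference_provenance = provenance),
            class = "height_age_estimate")
}

#' @export
print.height_age_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (95%% CI %s, %s)",
                                             format(x$ci_low), format(x$ci_high))
  se <- if (is.na(x$se)) "" else sprintf(", SE %.2f d", x$se)
  cat(sprintf("height-age: %s d%s%s [%s]\n", format(x$point), ci, se, x$method))
  invisible(x)
}

#' LMS z-score of a stature at a given age (L = 1)
#'
#' With the power parameter fixed at 1, the height-for-age z-score of a
#' stature `y` at age `t` is `(y / M(t) - 1) / S(t)`.
#'
#' @param y stature in cm.
#' @param age_days age in days (must be a table age).
#' @param ref a sex-combined [growth_reference()].
#' @return z-score (dimensionless).
#' @export
stature_to_z <- function(y, age_days, ref) {
  ms <- median_at(ref, age_days)
  (y / ms$M - 1) / ms$S
}

#' Stature corresponding to a z-score at a given age (L = 1)
#'
#' Inverse of [stature_to_z()]: `y = M(t) * (1 + z * S(t))`. This is the
#' back-calculation used when only a mean HAZ/LAZ is published.
#'
#' @param z z-score.
#' @inheritParams stature_to_z
#' @return Stature in cm.
#' @export
z_to_stature <- function(z, age_days, ref) {
  ms <- median_at(ref, age_days)
  ms$M * (1 + z * ms$S)
}

#' Resolve the measurement mode from the group's mean age
#'
#' Applies the WHO convention for the majority measurement: groups with
#' mean age at or above 731 days (2 y) are taken as measured by standing
#' height (majority HAZ), younger groups by recumbent length (majority
#' LAZ).
#'
#' @param mean_age_days mean age in days.
#' @return `"height"` or `"length"`.
#' @export
resolve_mode <- function(mean_age_days) {
  ifelse(mean_age_days >= 731, "height", "length")
}

resolved_mode <- function(s) {
  if (s$mode == "infer") resolve_mode(s$mean_age_days) else s$mode
}

#' Height-age from a group's mean stature
#'
#' The preferred derivation path: harmonize the reference to the group's
#' measurement mode, then look up the age whose median is nearest the
#' observed mean ([age_at_median()]). Reported CI bounds are pushed
#' through the same lookup (monotonicity preserves their order) and the
#' SE is recovered from the transformed CI width as
#' `(upper - lower) / (2 * 1.959964)`.
#'
#' @param s a [summary_stature()] with `metric = "stature"`.
#' @param ref a sex-combined [growth_reference()] (any mode mix; it is
#'   harmonized internally).
#' @param interpolate passed to [age_at_median()].
#' @return A `height_age_estimate` (point, SE and CI in days).
#' @export
height_age_from_mean_stature <- function(s, ref, interpolate = FALSE) {
  stopifnot(inherits(s, "summary_stature"))
  if (s$metric != "stature") stop("metric must be 'stature'", call. = FALSE)
  mode <- resolved_mode(s)
  href <- harmonize_mode(ref, mode)
  lookup <- function(x, what) {
    tryCatch(age_at_median(href, x, interpolate = interpolate),
             error = function(e) {
               stop("height-age lookup failed for the ", what, " (",
                    format(x), " cm): ", conditionMessage(e), call. = FALSE)
             })
  }
  point <- lookup(s$value, "mean")
  est <- height_age_estimate(point, method = "from_mean_stature",
                             provenance = attr(ref, "provenance"))
  if (!is.na(s$ci_low) && !is.na(s$ci_high)) {
    lo <- lookup(s$ci_low, "lower CI bound")
    hi <- lookup(s$ci_high, "upper CI bound")
    est$ci_low <- lo
    est$ci_high <- hi
    est$se <- (hi - lo) / (2 * Z95)
  }
  est
}

#' Height-age from a group's mean z-score
#'
#' Back-calculates the mean stature (and CI bounds) from the reported
#' mean HAZ/LAZ at the group's mean age, using the reference medians in
#' the mode the z-scores were computed against, then proceeds exactly as
#' [height_age_from_mean_stature()]. By construction the two paths give
#' identical height-ages for corresponding inputs.
#'
#' @param s a [summary_stature()] with `metric = "zscore"`.
#' @inheritParams height_age_from_mean_stature
#' @return A `height_age_estimate`.
#' @export
height_age_from_mean_z <- function(s, ref, interpolate = FALSE) {
  stopifnot(inherits(s, "summary_stature"))
  if (s$metric != "zscore") stop("metric must be 'zscore'", call. = FALSE)
  mode <- resolved_mode(s)
  # the z was computed against this mode's standard: back-calculate on it
  zref <- harmonize_mode(ref, mode)
  back <- function(z) if (is.na(z)) NA_real_ else z_to_stature(z, s$mean_age_days, zref)
  s2 <- summary_stature(metric = "stature", value = back(s$value),
                        ci_low = back(s$ci_low), ci_high = back(s$ci_high),
                        n = s$n, mean_age_days = s$mean_age_days,
                        proportion_female = s$proportion_female, mode = mode)
  est <- height_age_from_mean_stature(s2, ref, interpolate = interpolate)
  est$method <- "from_mean_z"
  est
}

#' Height-age from individual-level records
#'
#' Converts each child's stature to a height-age via a sex-specific (or
#' combined) mode-harmonized lookup and summarizes the cohort by the
#' arithmetic mean, with `SE = SD / sqrt(n)` and a normal 95% CI. Records
#' outside the reference range are reported together in a single error —
#' none are silently dropped.
#'
#' Note that individual height-ages implicitly hold each child to the
#' median trajectory, which is only a group-level expectation; deriving
#' the group height-age from the mean stature over a narrow age window
#' is the preferred approach, and this path is provided for comparison.
#'
#' @param records data frame with columns `age_days`, `sex` ("male"/
#'   "female"; ignored when `ref` is combined), `stature` (cm), `mode`
#'   ("length"/"height").
#' @param ref a [growth_reference()], either two-sex or combined.
#' @param interpolate passed to [age_at_median()].
#' @return A list with `per_record` (height-age in days per child) and
#'   `estimate` (a `height_age_estimate` with method `from_individuals`;
#'   SE and CI are absent when `n = 1`).
#' @export
height_age_from_individuals <- function(records, ref, interpolate = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("age_days", "stature", "mode") %in% names(records)))
  combined <- is_combined(ref)
  if (!combined && !"sex" %in% names(records)) {
    stop("records need a 'sex' column when the reference is not combined",
         call. = FALSE)
  }
  # pre-harmonize one lookup table per (sex, mode) actually present;
  # a single-sex slice is its own complete lookup table
  tables <- list()
  get_table <- function(sex, mode) {
    key <- paste(sex, mode, sep = "|")
    if (is.null(tables[[key]])) {
      sub <- if (combined) ref else {
        r <- as.data.frame(ref[ref$sex == sex, , drop = FALSE])
        if (nrow(r) == 0L) stop("sex '", sex, "' not present in the reference",
                                call. = FALSE)
        r$sex <- "combined"
        growth_reference(r, provenance = attr(ref, "provenance"),
                         combined = TRUE)
      }
      tables[[key]] <<- harmonize_mode(sub, mode)
    }
    tables[[key]]
  }
  ha <- rep(NA_real_, nrow(records))
  failures <- character(0)
  for (i in seq_len(nrow(records))) {
    sex <- if (combined) "combined" else records$sex[i]
    tab <- get_table(sex, records$mode[i])
    ha[i] <- tryCatch(age_at_median(tab, records$stature[i], interpolate = interpolate),
                      error = function(e) {
                        failures <<- c(failures,
                                       sprintf("record %d (%s cm): %s", i,
                                               format(records$stature[i]),
                                               conditionMessage(e)))
                        NA_real_
                      })
  }
  if (length(failures) > 0L) {
    stop("height-age lookup failed for ", length(failures), " record(s):\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  }
  n <- length(ha)
  point <- mean(ha)
  est <- height_age_estimate(point, method = "from_individuals",
                             provenance = attr(ref, "provenance"))
  if (n >= 2L) {
    est$se <- stats::sd(ha) / sqrt(n)
    est$ci_low <- point - Z95 * est$se
    est$ci_high <- point + Z95 * est$se
  }
  list(per_record = ha, estimate = est)
}

#' Summary moments of a distribution of values
#'
#' Reports the mean, median, sample SD (n - 1 divisor), skewness
#' `m3 / m2^(3/2)` and non-excess kurtosis `m4 / m2^2` (a normal sample
#' gives about 3), where `m_k` are the central sample moments with
#' divisor `n`. Used to compare the shapes of height, z-score and
#' height-age distributions in a cohort.
#'
#' @param values numeric vector, `n >= 2` (`n >= 3` for skewness,
#'   `n >= 4` for kurtosis).
#' @return A list with `mean`, `median`, `sd`, `skewness`, `kurtosis`
#'   and `n`. Skewness/kurtosis are `NA` (with a warning) when the
#'   values have zero variance.
#' @export
distribution_moments <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("at least 2 values are required", call. = FALSE)
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  skew <- kurt <- NA_real_
  if (m2 == 0) {
    warning("zero variance: skewness and kurtosis are undefined")
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  list(mean = m, median = stats::median(values), sd = stats::sd(values),
       skewness = skew, kurtosis = kurt, n = n)
}
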