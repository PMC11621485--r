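# LMS growth-reference handling: loading, validation, sex combination,
# length/height harmonization, and median <-> age lookups.

#' Construct a growth reference from a data frame of LMS rows
#'
#' A growth reference is a per-sex, per-day table of LMS parameters
#' (power `L`, median `M` in cm, coefficient of variation `S`) together
#' with the measurement mode of each row (recumbent `length` below 731
#' days in the native WHO layout, standing `height` at or above).
#' This implementation assumes `L = 1` everywhere, as in the WHO 0-5 y
#' length/height-for-age table, so the z-score is `(y/M - 1)/S`.
#'
#' @param rows data frame with columns `sex` ("male"/"female"), `age_days`
#'   (integer, >= 0), `L`, `M` (cm), `S`, `mode` ("length"/"height").
#' @param provenance free-text label describing the source of the table.
#' @param combined logical; `TRUE` when the sexes have already been merged
#'   into a single weighted table.
#' @return An object of class `growth_reference` (a data frame with
#'   attributes `provenance` and `combined`), rows ordered by sex then age.
#' @seealso [load_reference()], [combine_sexes()], [harmonize_mode()]
#' @export
growth_reference <- function(rows, provenance = "unspecified", combined = FALSE) {
  required <- c("sex", "age_days", "L", "M", "S", "mode")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0L) {
    stop("reference is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- as.data.frame(rows)[required]
  rows$sex <- as.character(rows$sex)
  rows$mode <- as.character(rows$mode)
  rows$age_days <- as.integer(rows$age_days)
  rows <- rows[order(rows$sex, rows$age_days), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows,
            provenance = provenance,
            combined = isTRUE(combined),
            class = c("growth_reference", "data.frame"))
}

#' @export
print.growth_reference <- function(x, ...) {
  cat(sprintf("<growth_reference> %d rows | sexes: %s | ages %d-%d d | %s%s\n",
              nrow(x), paste(unique(x$sex), collapse = "+"),
              min(x$age_days), max(x$age_days),
              attr(x, "provenance"),
              if (isTRUE(attr(x, "combined"))) " | combined" else ""))
  invisible(x)
}

is_combined <- function(ref) isTRUE(attr(ref, "combined"))

#' Validate a growth reference
#'
#' Checks the structural invariants a reference must satisfy before any
#' lookup: known sex and mode labels, positive `M` and `S`, `L = 1` on
#' every row, unique contiguous daily ages spanning a common range per
#' sex, and a strictly increasing median within each sex-by-mode segment
#' (the 0.7 cm length-to-height drop at 731 days makes the full sequence
#' non-monotone in the native layout, which is why monotonicity is only
#' required within a mode segment here).
#'
#' @param ref a [growth_reference()].
#' @return `ref`, invisibly, if valid; otherwise an error naming the
#'   first offending row.
#' @export
validate_reference <- function(ref) {
  stopifnot(inherits(ref, "growth_reference"))
  if (is_combined(ref)) {
    if (!all(ref$sex == "combined")) {
      stop("a combined reference must carry sex = 'combined' on every row",
           call. = FALSE)
    }
  } else if (!all(ref$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!all(ref$mode %in% c("length", "height"))) {
    stop("mode must be 'length' or 'height'", call. = FALSE)
  }
  if (any(ref$M <= 0)) stop("median M must be positive", call. = FALSE)
  if (any(ref$S <= 0)) stop("coefficient of variation S must be positive", call. = FALSE)
  if (any(ref$L != 1)) {
    stop("power L must equal 1 on every row; this implementation supports ",
         "L = 1 references only (WHO 0-5 y length/height-for-age)", call. = FALSE)
  }
  if (any(ref$age_days < 0)) stop("age_days must be >= 0", call. = FALSE)
  spans <- lapply(split(ref, ref$sex), function(d) {
    a <- d$age_days
    if (anyDuplicated(a)) {
      stop("duplicated age_days within sex '", d$sex[1], "'", call. = FALSE)
    }
    if (!identical(a, seq.int(min(a), max(a)))) {
      stop("age_days must be contiguous daily values within sex '",
           d$sex[1], "'", call. = FALSE)
    }
    # strict monotonicity of the median within each mode segment
    seg <- cumsum(c(TRUE, d$mode[-1] != d$mode[-nrow(d)]))
    for (s in split(d, seg)) {
      dm <- diff(s$M)
      if (any(dm <= 0)) {
        bad <- s$age_days[which(dm <= 0)[1] + 1L]
        stop("median M not strictly increasing within sex '", d$sex[1],
             "', mode '", s$mode[1], "': first offending age ", bad, " d",
             call. = FALSE)
      }
    }
    range(a)
  })
  if (length(unique(spans)) != 1L) {
    stop("all sexes must span the same [min, max] age range", call. = FALSE)
  }
  invisible(ref)
}

#' Load an LMS growth reference from a delimited text file
#'
#' Reads a comma- or tab-delimited table with a header in either the
#' native WHO "lenanthro" layout (columns `sex` coded 1 = male /
#' 2 = female, `_agedays` or `age_days`, `l`, `m`, `s`, optional `loh`)
#' or a generic layout with explicit `male`/`female` labels and
#' `length`/`height` mode labels. When the mode column is absent it is
#' inferred from the WHO convention: recumbent length below 731 days,
#' standing height at or above. Users exporting the WHO `lenanthro.dta`
#' file can do so with, e.g., `haven::read_dta()` followed by
#' `write.csv()`, or Stata's `export delimited`.
#'
#' @param path path to the delimited file.
#' @param dialect `"who_lenanthro"` (numeric sex codes) or
#'   `"generic_delimited"` (explicit labels).
#' @return A validated [growth_reference()] ordered by sex then age.
#' @export
load_reference <- function(path, dialect = c("who_lenanthro", "generic_delimited")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  raw <- read_delimited(path)
  names(raw) <- tolower(names(raw))
  names(raw)[names(raw) %in% c("_agedays", "agedays")] <- "age_days"
  required <- c("sex", "age_days", "l", "m", "s")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("reference file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sex <- raw$sex
  if (dialect == "who_lenanthro") {
    sex <- c("1" = "male", "2" = "female")[as.character(sex)]
    if (anyNA(sex)) stop("WHO dialect expects sex coded 1 (male) / 2 (female)",
                         call. = FALSE)
  } else {
    sex <- tolower(as.character(sex))
    if (!all(sex %in% c("male", "female"))) {
      stop("generic dialect requires explicit sex labels 'male'/'female'",
           call. = FALSE)
    }
  }
  mode_col <- intersect(c("loh", "mode"), names(raw))
  if (length(mode_col) > 0L) {
    mode <- tolower(as.character(raw[[mode_col[1]]]))
    mode[mode %in% c("l")] <- "length"
    mode[mode %in% c("h")] <- "height"
  } else {
    mode <- ifelse(raw$age_days < 731, "length", "height")
  }
  ref <- growth_reference(
    data.frame(sex = sex, age_days = raw$age_days, L = raw$l, M = raw$m,
               S = raw$s, mode = mode),
    provenance = basename(path)
  )
  validate_reference(ref)
}

# comma or tab, sniffed from the header line
read_delimited <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Combine the two sexes of a reference into one weighted table
#'
#' Merges the male and female rows age-by-age using a sex-weighted (or,
#' at ratio 0.5, simple) mean of the LMS parameters: the combined median
#' is `p * M_female + (1 - p) * M_male` and likewise for `S`, where `p`
#' is the proportion of females in the group under study. Group-level
#' height-age lookups require a combined table unless results are
#' reported disaggregated by sex.
#'
#' @param ref a validated two-sex [growth_reference()].
#' @param proportion_female fraction of females in `[0, 1]`.
#' @return A combined `growth_reference` with one row per age
#'   (`sex = "combined"`), mode preserved.
#' @export
combine_sexes <- function(ref, proportion_female = 0.5) {
  validate_reference(ref)
  if (is_combined(ref)) stop("reference is already sex-combined", call. = FALSE)
  if (!all(c("male", "female") %in% ref$sex)) {
    stop("combine_sexes requires both sexes in the reference", call. = FALSE)
  }
  if (!is.numeric(proportion_female) || proportion_female < 0 || proportion_female > 1) {
    stop("proportion_female must lie in [0, 1]", call. = FALSE)
  }
  f <- ref[ref$sex == "female", ]
  m <- ref[ref$sex == "male", ]
  stopifnot(identical(f$age_days, m$age_days), identical(f$mode, m$mode))
  p <- proportion_female
  out <- data.frame(sex = "combined", age_days = f$age_days, L = 1,
                    M = p * f$M + (1 - p) * m$M,
                    S = p * f$S + (1 - p) * m$S,
                    mode = f$mode)
  res <- growth_reference(out, provenance = attr(ref, "provenance"), combined = TRUE)
  validate_reference(res)
  res
}

#' Harmonize a reference to a single measurement mode
#'
#' Re-expresses every median on the scale of `target_mode`, using the
#' WHO convention that standing height measures about 0.7 cm less than
#' recumbent length in the same child: rows recorded as length get 0.7 cm
#' subtracted when the target is height, and rows recorded as height get
#' 0.7 cm added when the target is length. Only the medians are shifted;
#' the coefficient of variation `S` is left untouched. After the shift
#' the full median sequence must be strictly increasing (the shift closes
#' the two-year discontinuity), and this is re-checked.
#'
#' This is the core of the two-year workflow: when a group measured by
#' standing height at about age 2 y has faltered enough that its
#' height-age falls below 731 days, its observed mean must be compared
#' against medians expressed as standing height, not recumbent length.
#'
#' @param ref a validated [growth_reference()].
#' @param target_mode `"length"` or `"height"`.
#' @return A `growth_reference` with all rows in `target_mode`.
#' @export
harmonize_mode <- function(ref, target_mode = c("height", "length")) {
  target_mode <- match.arg(target_mode)
  validate_reference(ref)
  out <- ref
  shift <- numeric(nrow(out))
  shift[out$mode == "length" & target_mode == "height"] <- -0.7
  shift[out$mode == "height" & target_mode == "length"] <- +0.7
  out$M <- out$M + shift
  out$mode <- target_mode
  res <- growth_reference(as.data.frame(out),
                          provenance = attr(ref, "provenance"),
                          combined = is_combined(ref))
  for (d in split(res, res$sex)) {
    if (any(diff(d$M) <= 0)) {
      bad <- d$age_days[which(diff(d$M) <= 0)[1] + 1L]
      stop("mode harmonization broke monotonicity at age ", bad,
           " d (sex ", d$sex[1], ")", call. = FALSE)
    }
  }
  res
}

#' Median stature (and coefficient of variation) at an exact age
#'
#' Non-integer ages (e.g. month-converted) are rounded to the nearest
#' table day.
#'
#' @param ref a sex-combined [growth_reference()].
#' @param age_days age in days within the table span.
#' @return A list with elements `M` (cm) and `S`.
#' @export
median_at <- function(ref, age_days) {
  stopifnot(inherits(ref, "growth_reference"))
  if (!is_combined(ref)) stop("median_at requires a sex-combined reference", call. = FALSE)
  i <- match(as.integer(round(age_days)), ref$age_days)
  if (anyNA(i)) {
    stop("age ", age_days[which(is.na(i))[1]], " d outside reference span [",
         min(ref$age_days), ", ", max(ref$age_days), "]", call. = FALSE)
  }
  list(M = ref$M[i], S = ref$S[i])
}

#' Height-age lookup: age at which the reference median equals a stature
#'
#' Returns the age (in days) whose median stature is closest in absolute
#' difference to the observed group mean — the defining operation of
#' height-age. Lookups run on the table's native daily grid; exact ties
#' between two neighbouring days are broken toward the younger age. With
#' `interpolate = TRUE` a fractional day is returned by linear
#' interpolation between the bracketing medians (nearest-row remains the
#' canonical behaviour).
#'
#' A stature below the day-0 median (beyond a tolerance of half the
#' first median step) raises an underflow error: the 0-5 y table cannot
#' assign a height-age to a group whose mean stature is smaller than the
#' median at birth, a recognised limitation of the method for severely
#' faltered cohorts. Statures above the table maximum (same half-step
#' tolerance) raise an overflow error.
#'
#' @param ref a sex-combined, mode-harmonized [growth_reference()] (all
#'   rows in one measurement mode).
#' @param stature observed mean stature in cm, on the same mode scale as
#'   `ref`.
#' @param interpolate logical; return a fractional day by linear
#'   interpolation instead of the nearest table row.
#' @return Age in days (integer unless `interpolate = TRUE`).
#' @export
age_at_median <- function(ref, stature, interpolate = FALSE) {
  stopifnot(inherits(ref, "growth_reference"), length(stature) == 1L,
            is.finite(stature))
  if (!is_combined(ref)) {
    stop("age_at_median requires a sex-combined reference", call. = FALSE)
  }
  if (length(unique(ref$mode)) != 1L) {
    stop("age_at_median requires a mode-harmonized reference; ",
         "call harmonize_mode() first", call. = FALSE)
  }
  M <- ref$M
  n <- length(M)
  if (stature < M[1] - 0.5 * (M[2] - M[1])) {
    stop("underflow: stature ", format(stature), " cm is below the day-",
         ref$age_days[1], " median (", format(M[1]), " cm); the 0-5 y ",
         "reference cannot assign a height-age below its youngest age",
         call. = FALSE)
  }
  if (stature > M[n] + 0.5 * (M[n] - M[n - 1])) {
    stop("overflow: stature ", format(stature), " cm exceeds the maximum ",
         "reference median (", format(M[n]), " cm at age ", ref$age_days[n],
         " d)", call. = FALSE)
  }
  if (interpolate) {
    return(stats::approx(M, ref$age_days, xout = min(max(stature, M[1]), M[n]),
                         ties = "ordered")$y)
  }
  # which.min takes the first minimum; rows are age-ascending, so an exact
  # tie between two equidistant medians resolves to the younger age
  ref$age_days[which.min(abs(M - stature))]
}
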