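# Intervention-vs-control effect estimates: mean differences, changes in
# height-age, and the proportion of maximal benefit (PMB) with 95% CIs.

#' Mean difference of two independent group means with 95% CI
#'
#' `MD = a_mean - b_mean`, with a normal-approximation CI
#' `MD +/- 1.959964 * sqrt(a_se^2 + b_se^2)` treating the groups as
#' independent. Used for both the z-score MD and the height-age MD
#' (intervention minus control).
#'
#' @param a_mean,a_se mean and SE of the first (intervention) group.
#' @param b_mean,b_se mean and SE of the second (control) group.
#' @return A list with `md`, `se`, `ci_low`, `ci_high`.
#' @export
mean_difference <- function(a_mean, a_se, b_mean, b_se) {
  if (isTRUE(a_se < 0) || isTRUE(b_se < 0)) {
    stop("SEs must be non-negative", call. = FALSE)
  }
  md <- a_mean - b_mean
  se <- sqrt(a_se^2 + b_se^2)
  list(md = md, se = se, ci_low = md - Z95 * se, ci_high = md + Z95 * se)
}

#' Change in height-age between two timepoints of one arm
#'
#' `delta = endline - baseline` (days), with
#' `SE = sqrt(se_b^2 + se_e^2 - 2 * corr * se_b * se_e)`. The
#' baseline-endline correlation of the two group means defaults to 0
#' (independence); for repeated measures on the same children the true
#' correlation is typically positive, which would shrink the SE, so the
#' default is the wider (conservative) choice.
#'
#' @param baseline,endline `height_age_estimate` objects carrying SEs.
#' @param corr within-arm correlation of the two estimates, in `[-1, 1]`.
#' @return A list with `delta` (days) and `se` (`NA` when either SE is
#'   missing).
#' @export
change_in_height_age <- function(baseline, endline, corr = 0) {
  stopifnot(inherits(baseline, "height_age_estimate"),
            inherits(endline, "height_age_estimate"))
  if (!is.finite(corr) || corr < -1 || corr > 1) {
    stop("corr must lie in [-1, 1]", call. = FALSE)
  }
  delta <- endline$point - baseline$point
  se <- if (is.na(baseline$se) || is.na(endline$se)) NA_real_ else
    sqrt(baseline$se^2 + endline$se^2 - 2 * corr * baseline$se * endline$se)
  list(delta = delta, se = se)
}

#' Proportion of maximal benefit (PMB)
#'
#' Scores an intervention's effect on linear growth against the
#' biologically optimal rate for the group's starting height-age:
#'
#' `PMB = (dHA_I - dHA_C) / (dCA_I - dHA_C) * 100`
#'
#' where `dHA_I` and `dHA_C` are the intervention and control groups'
#' changes in height-age over the observation period and `dCA_I` is the
#' intervention group's change in chronologic age — the theoretical
#' maximum, since optimal growth advances height-age one day per day of
#' chronologic age. 0% means no effect beyond control; 100% means the
#' intervention group grew at the optimal rate. All three deltas must be
#' in the same time unit; the value is unit-invariant.
#'
#' Values outside `[0, 100]` are mathematically possible (e.g., a harmful
#' intervention, or growth beyond the skeletal-age expectation) and are
#' returned as-is with `plausible = FALSE` rather than clamped; a PMB
#' near or above 100% from a short nutrition-specific intervention
#' warrants scrutiny of the trial itself.
#'
#' @param delta_ha_intervention change in height-age, intervention arm.
#' @param delta_ha_control change in height-age, control arm.
#' @param delta_ca_intervention change in chronologic age, intervention
#'   arm (> 0), same unit as the height-age deltas.
#' @return A list with `pmb` (percent) and `plausible` (logical,
#'   `TRUE` when 0 <= PMB <= 100).
#' @export
pmb <- function(delta_ha_intervention, delta_ha_control, delta_ca_intervention) {
  if (delta_ca_intervention <= 0) {
    stop("change in chronologic age must be positive", call. = FALSE)
  }
  denom <- delta_ca_intervention - delta_ha_control
  if (denom <= 0) {
    stop("degenerate control: control grew at or above the optimal rate ",
         "(change in height-age >= change in chronologic age), so the PMB ",
         "denominator is not positive", call. = FALSE)
  }
  value <- (delta_ha_intervention - delta_ha_control) / denom * 100
  list(pmb = value, plausible = value >= 0 && value <= 100)
}

#' 95% CI for the PMB by bound substitution
#'
#' The PMB numerator is the mean difference between the two arms' changes
#' in height-age, so its CI bounds are obtained by substituting the 95%
#' bounds of that MD into the numerator while holding the denominator
#' fixed: `bound = MD_bound / (dCA_I - dHA_C) * 100`.
#'
#' @param delta_ha_md_ci numeric length-2, the 95% CI (low, high) of the
#'   MD between the arms' changes in height-age, in days.
#' @inheritParams pmb
#' @return A list with `ci_low` and `ci_high` in percent.
#' @export
pmb_ci <- function(delta_ha_md_ci, delta_ha_control, delta_ca_intervention) {
  stopifnot(length(delta_ha_md_ci) == 2L, delta_ha_md_ci[1] <= delta_ha_md_ci[2])
  if (delta_ca_intervention <= 0) {
    stop("change in chronologic age must be positive", call. = FALSE)
  }
  denom <- delta_ca_intervention - delta_ha_control
  if (denom <= 0) {
    stop("degenerate control: control grew at or above the optimal rate",
         call. = FALSE)
  }
  list(ci_low = delta_ha_md_ci[1] / denom * 100,
       ci_high = delta_ha_md_ci[2] / denom * 100)
}

#' Table of effect estimates for the arms of one or more trials
#'
#' For every trial and assessment time in `arms`, derives height-ages
#' for each arm summary, then reports per intervention-vs-control
#' contrast: the MD on the native metric scale (z or cm), the height-age
#' MD (days), the MD between the arms' changes in height-age since
#' baseline, and the PMB with its bound-substitution CI. When a baseline
#' height-age cannot be derived (typically an intervention starting at
#' birth, where the group mean falls below the day-0 median), the PMB is
#' reported as `NA` with the reason, and the assessment-time MDs are
#' still reported.
#'
#' @param arms data frame with one row per trial x arm x timepoint:
#'   columns `trial`, `arm`, `role` ("intervention"/"control"),
#'   `timepoint` ("baseline"/"endline"/"followup"), `mean_age_days`, `n`,
#'   `metric` ("stature"/"zscore"), `value`, `ci_low`, `ci_high`,
#'   `proportion_female`, `mode`.
#' @param ref a two-sex [growth_reference()]; it is sex-weighted per
#'   trial using `proportion_female` before lookups.
#' @param corr baseline-endline correlation passed to
#'   [change_in_height_age()].
#' @param interpolate passed to the height-age lookups.
#' @return A data frame, one row per trial x intervention arm x
#'   assessment time (`endline`, and `followup` when present), with the
#'   effect estimates and their CIs, a `pmb_reason` column explaining any
#'   `NA` PMB, and a `pmb_plausible` flag.
#' @export
effect_table <- function(arms, ref, corr = 0, interpolate = FALSE) {
  needed <- c("trial", "arm", "role", "timepoint", "mean_age_days", "n",
              "metric", "value", "ci_low", "ci_high", "proportion_female", "mode")
  missing_cols <- setdiff(needed, names(arms))
  if (length(missing_cols) > 0L) {
    stop("arms table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (trial in unique(arms$trial)) {
    tr <- arms[arms$trial == trial, , drop = FALSE]
    pf <- tr$proportion_female[1]
    cref <- if (is_combined(ref)) ref else combine_sexes(ref, pf)
    ctrl <- tr[tr$role == "control", , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop("trial '", trial, "' has no control arm", call. = FALSE)
    }
    for (iarm in unique(tr$arm[tr$role == "intervention"])) {
      ia <- tr[tr$arm == iarm, , drop = FALSE]
      for (tp in intersect(c("endline", "followup"), ia$timepoint)) {
        out[[length(out) + 1L]] <-
          contrast_row(trial, iarm, tp, ia, ctrl, cref, corr, interpolate)
      }
    }
  }
  if (length(out) == 0L) {
    stop("no intervention-vs-control contrast with an endline found", call. = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# one intervention-vs-control contrast at one assessment time
contrast_row <- function(trial, iarm, tp, ia, ctrl, cref, corr, interpolate) {
  derive <- function(row) {
    s <- summary_stature(metric = row$metric, value = row$value,
                         ci_low = row$ci_low, ci_high = row$ci_high,
                         n = row$n, mean_age_days = row$mean_age_days,
                         proportion_female = row$proportion_female,
                         mode = row$mode)
    if (row$metric == "zscore") height_age_from_mean_z(s, cref, interpolate)
    else height_age_from_mean_stature(s, cref, interpolate)
  }
  pick <- function(d, tp) {
    r <- d[d$timepoint == tp, , drop = FALSE]
    if (nrow(r) == 0L) stop("trial '", trial, "', arm '", d$arm[1],
                            "': missing timepoint '", tp, "'", call. = FALSE)
    r[1, , drop = FALSE]
  }
  i_end <- pick(ia, tp)
  c_end <- pick(ctrl, tp)
  se_of <- function(row) {
    if (is.na(row$ci_low) || is.na(row$ci_high)) NA_real_
    else (row$ci_high - row$ci_low) / (2 * Z95)
  }
  metric_md <- mean_difference(i_end$value, se_of(i_end),
                               c_end$value, se_of(c_end))
  ha_i_end <- derive(i_end)
  ha_c_end <- derive(c_end)
  ha_md <- mean_difference(ha_i_end$point, ha_i_end$se,
                           ha_c_end$point, ha_c_end$se)

  pmb_val <- pmb_lo <- pmb_hi <- dha_md <- dha_lo <- dha_hi <- NA_real_
  pmb_ok <- NA
  reason <- ""
  has_base <- all(c("baseline" %in% ia$timepoint, "baseline" %in% ctrl$timepoint))
  if (!has_base) {
    reason <- "no baseline summary for both arms"
  } else {
    base_res <- tryCatch({
      i_base <- pick(ia, "baseline")
      c_base <- pick(ctrl, "baseline")
      ha_i_base <- derive(i_base)
      ha_c_base <- derive(c_base)
      d_i <- change_in_height_age(ha_i_base, ha_i_end, corr)
      d_c <- change_in_height_age(ha_c_base, ha_c_end, corr)
      dca <- i_end$mean_age_days - i_base$mean_age_days
      md <- mean_difference(d_i$delta, d_i$se, d_c$delta, d_c$se)
      p <- pmb(d_i$delta, d_c$delta, dca)
      ci <- if (is.na(md$ci_low)) list(ci_low = NA_real_, ci_high = NA_real_)
            else pmb_ci(c(md$ci_low, md$ci_high), d_c$delta, dca)
      list(p = p, ci = ci, md = md)
    }, error = function(e) conditionMessage(e))
    if (is.character(base_res)) {
      reason <- base_res
    } else {
      pmb_val <- base_res$p$pmb
      pmb_ok <- base_res$p$plausible
      pmb_lo <- base_res$ci$ci_low
      pmb_hi <- base_res$ci$ci_high
      dha_md <- base_res$md$md
      dha_lo <- base_res$md$ci_low
      dha_hi <- base_res$md$ci_high
    }
  }
  data.frame(trial = trial, arm = iarm, assessment = tp,
             metric = i_end$metric,
             metric_md = metric_md$md, metric_md_low = metric_md$ci_low,
             metric_md_high = metric_md$ci_high,
             ha_intervention = ha_i_end$point, ha_control = ha_c_end$point,
             ha_md = ha_md$md, ha_md_low = ha_md$ci_low,
             ha_md_high = ha_md$ci_high,
             delta_ha_md = dha_md, delta_ha_md_low = dha_lo,
             delta_ha_md_high = dha_hi,
             pmb = pmb_val, pmb_low = pmb_lo, pmb_high = pmb_hi,
             pmb_plausible = pmb_ok, pmb_reason = reason,
             stringsAsFactors = FALSE)
}
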