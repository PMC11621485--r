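# Synthetic growth references, cohorts and two-arm trials with known
# ground truth, so the whole toolchain is testable without external data.

#' Generate a synthetic LMS growth reference
#'
#' Builds a daily two-sex reference on `0..max_age_days` with `L = 1`
#' everywhere and an underlying median curve
#' `M(t) = M0 + a * t + b * (1 - exp(-k * t))` (female scale; males are
#' offset by `sex_offset` cm). The curve is strictly increasing whenever
#' `a > 0` and `b * k >= 0`: growth velocity starts at `a + b * k` and
#' decays toward `a`, mimicking the fast-then-slowing pattern of early
#' childhood. With `discontinuity = TRUE` the rows at and above 731 days
#' are expressed as standing height by subtracting 0.7 cm from the
#' underlying (length-scale) median, reproducing the two-year
#' length-to-height switch of the WHO layout; below 731 days rows carry
#' `mode = "length"`.
#'
#' Defaults give a curve of WHO-like scale: about 49 cm at birth, about
#' 87 cm at 2 y, and about 0.11 cm/d velocity in early infancy slowing
#' to 0.025 cm/d, with a 3.5% coefficient of variation.
#'
#' @param max_age_days last tabulated age (default 1856, the WHO 0-5 y
#'   span).
#' @param M0 female median at birth, cm.
#' @param a linear growth rate, cm/day (late-childhood velocity).
#' @param b,k saturating component: amplitude (cm) and rate (1/day) of
#'   the early-growth excess.
#' @param cv_S coefficient of variation, either a constant or a vector
#'   of length `max_age_days + 1`.
#' @param sex_offset male minus female median, cm.
#' @param discontinuity apply the 0.7 cm length-to-height drop at 731 d.
#' @return A validated two-sex [growth_reference()].
#' @export
make_reference <- function(max_age_days = 1856, M0 = 49.1, a = 0.025,
                           b = 21, k = 0.004, cv_S = 0.035,
                           sex_offset = 0.8, discontinuity = TRUE) {
  stopifnot(max_age_days >= 1, M0 > 0)
  if (a <= 0 || b * k < 0) {
    stop("median function must be strictly increasing: need a > 0 and b*k >= 0",
         call. = FALSE)
  }
  t <- 0:max_age_days
  base <- M0 + a * t + b * (1 - exp(-k * t))
  S <- rep_len(cv_S, length(t))
  one_sex <- function(sex, offset) {
    M <- base + offset
    mode <- rep("length", length(t))
    if (discontinuity && max_age_days >= 731) {
      at2y <- t >= 731
      M[at2y] <- M[at2y] - 0.7
      mode[at2y] <- "height"
    }
    data.frame(sex = sex, age_days = t, L = 1, M = M, S = S, mode = mode)
  }
  ref <- growth_reference(rbind(one_sex("female", 0), one_sex("male", sex_offset)),
                          provenance = "synthetic")
  validate_reference(ref)
  ref
}

#' Simulate an individual-level cohort against a reference
#'
#' Draws ages uniformly on `age_range`, z-scores from
#' `Normal(target_z_mean, z_sd)`, and sets each child's stature to
#' `M(t) * (1 + z * S(t))` using the child's sex-specific row in the
#' mode native to the drawn age. Sexes are assigned Bernoulli(0.5).
#'
#' @param ref a two-sex [growth_reference()].
#' @param n cohort size.
#' @param target_z_mean,z_sd parameters of the z-score distribution.
#' @param age_range integer length-2 vector, inclusive day range within
#'   the reference span.
#' @param seed integer seed for reproducibility.
#' @return A data frame of individual records (`age_days`, `sex`,
#'   `stature`, `mode`, and the generating `z`).
#' @export
simulate_cohort <- function(ref, n, target_z_mean = 0, z_sd = 1,
                            age_range = range(ref$age_days), seed = 1L) {
  validate_reference(ref)
  stopifnot(n >= 1, length(age_range) == 2L,
            age_range[1] >= min(ref$age_days),
            age_range[2] <= max(ref$age_days))
  set.seed(seed)
  days <- seq.int(age_range[1], age_range[2])
  age <- days[sample.int(length(days), n, replace = TRUE)]
  sex <- sample(c("male", "female"), n, replace = TRUE)
  z <- stats::rnorm(n, target_z_mean, z_sd)
  key <- paste(ref$sex, ref$age_days)
  i <- match(paste(sex, age), key)
  stature <- ref$M[i] * (1 + z * ref$S[i])
  data.frame(age_days = age, sex = sex, stature = stature,
             mode = ref$mode[i], z = z)
}

#' Simulate a two-arm trial summary with known true PMB
#'
#' Generates baseline and endline summary records for a control and an
#' intervention arm under the generative inverse of the PMB definition:
#' both arms start at the same baseline height-age `h0`; over an
#' observation period of `delta_ca` days of chronologic age, the control
#' arm's height-age advances by `r_c * delta_ca` (a fraction of the
#' optimal one-day-per-day rate) and the intervention arm's by
#' `(r_c + true_pmb * (1 - r_c)) * delta_ca`, so that the true PMB is
#' exactly `100 * true_pmb`. Arm mean statures are placed on the
#' (sex-combined, mode-harmonized) median at the target height-age, and
#' sampling noise for each arm mean is added on the stature scale with
#' `SE = z_sd * S(t) * M(t) / sqrt(n)`; reported CIs are the mean
#' +/- 1.959964 SE. `z_sd = 0` gives noise-free records that recover the
#' true PMB to lookup resolution.
#'
#' @param ref a two-sex [growth_reference()].
#' @param n_per_arm children per arm.
#' @param baseline_age_days mean chronologic age at baseline.
#' @param delta_ca observation period, days.
#' @param r_c control arm's height-age growth fraction in `(0, 1]`.
#' @param true_pmb true proportion of maximal benefit in `[0, 1]`.
#' @param z_sd dispersion of the underlying z-scores (0 = noise-free).
#' @param baseline_height_age_days baseline height-age `h0`; defaults to
#'   `r_c * baseline_age_days` (an arm that has grown at the control
#'   rate since birth).
#' @param proportion_female sex ratio of both arms.
#' @param trial label for the generated records.
#' @param seed integer seed.
#' @return A list with `records` (a long-format trial summary data frame
#'   in the pipeline schema) and `true_pmb` (percent).
#' @export
simulate_trial <- function(ref, n_per_arm = 500, baseline_age_days = 365,
                           delta_ca = 180, r_c = 0.5, true_pmb = 0.25,
                           z_sd = 1,
                           baseline_height_age_days = round(r_c * baseline_age_days),
                           proportion_female = 0.5, trial = "synthetic_trial",
                           seed = 1L) {
  validate_reference(ref)
  stopifnot(r_c > 0, r_c <= 1, true_pmb >= 0, true_pmb <= 1, delta_ca > 0,
            z_sd >= 0, n_per_arm >= 1)
  set.seed(seed)
  h0 <- baseline_height_age_days
  targets <- data.frame(
    arm = rep(c("control", "intervention"), each = 2L),
    role = rep(c("control", "intervention"), each = 2L),
    timepoint = rep(c("baseline", "endline"), 2L),
    mean_age_days = rep(c(baseline_age_days, baseline_age_days + delta_ca), 2L),
    height_age = c(h0, h0 + r_c * delta_ca,
                   h0, h0 + (r_c + true_pmb * (1 - r_c)) * delta_ca)
  )
  span <- range(ref$age_days)
  if (any(targets$height_age < span[1] | targets$height_age > span[2]) ||
      any(targets$mean_age_days > span[2])) {
    stop("implied ages or height-ages fall outside the reference span",
         call. = FALSE)
  }
  cref <- combine_sexes(ref, proportion_female)
  rows <- lapply(seq_len(nrow(targets)), function(j) {
    tg <- targets[j, ]
    mode <- resolve_mode(tg$mean_age_days)
    href <- harmonize_mode(cref, mode)
    # mean stature sits on the median at the target height-age
    y <- stats::approx(href$age_days, href$M, xout = tg$height_age)$y
    ms <- median_at(cref, round(tg$mean_age_days))
    se <- z_sd * ms$S * ms$M / sqrt(n_per_arm)
    obs <- y + if (se > 0) stats::rnorm(1L, 0, se) else 0
    data.frame(trial = trial, arm = tg$arm, role = tg$role,
               timepoint = tg$timepoint, scheduled_age_days = tg$mean_age_days,
               mean_age_days = tg$mean_age_days, n = n_per_arm,
               metric = "stature", value = obs,
               ci_low = obs - Z95 * se, ci_high = obs + Z95 * se,
               proportion_female = proportion_female, mode = mode)
  })
  list(records = do.call(rbind, rows), true_pmb = 100 * true_pmb)
}
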