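# Shared synthetic fixtures, built in code.

# toy linear reference "R0": ages 0-100 d, M(t) = 50 + 0.1 t cm, S = 0.04,
# both sexes identical, recumbent length throughout
toy_ref <- function() {
  make_reference(max_age_days = 100, M0 = 50, a = 0.1, b = 0, k = 0,
                 cv_S = 0.04, sex_offset = 0, discontinuity = FALSE)
}

toy_combined <- function() combine_sexes(toy_ref(), 0.5)

# toy lookup table: combined and already in a single mode
toy_lookup <- function(mode = "length") harmonize_mode(toy_combined(), mode)

# WHO-like synthetic standard: daily 0-1856 d, two sexes, 0.7 cm
# length-to-height switch at 731 d
who_like_ref <- function() make_reference()

# independent nearest-row oracle: exhaustive scan over all rows, ties to
# the younger age (ages are sorted ascending within the table)
oracle_nearest_age <- function(ref, stature) {
  d <- abs(ref$M - stature)
  ref$age_days[order(d, ref$age_days)][1]
}

# random strictly-monotone combined single-mode reference for property tests
random_monotone_ref <- function(n_ages = 60, seed = 1) {
  set.seed(seed)
  M <- 45 + cumsum(stats::runif(n_ages + 1, 0.01, 0.3))
  growth_reference(
    data.frame(sex = "combined", age_days = 0:n_ages, L = 1, M = M,
               S = 0.04, mode = "length"),
    provenance = "random", combined = TRUE)
}
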