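test_that("z-score machinery matches the L = 1 LMS formulas and inverts", {
  c0 <- toy_combined()
  expect_equal(stature_to_z(55, 50, c0), 0)
  expect_equal(stature_to_z(52.8, 50, c0), -1)
  expect_equal(z_to_stature(0, 50, c0), 55)
  expect_equal(z_to_stature(-2, 50, c0), 50.6)
  expect_equal(z_to_stature(1, 0, c0), 52)

  # round trip identity over all ages x z in [-4, 4]
  zs <- seq(-4, 4, by = 0.25)
  for (z in zs) {
    back <- stature_to_z(z_to_stature(z, c0$age_days, c0), c0$age_days, c0)
    expect_equal(back, rep(z, nrow(c0)), tolerance = 1e-9)
  }
  expect_error(stature_to_z(55, 500, c0), "span")
})

test_that("measurement mode resolves from mean age at the two-year rule", {
  expect_equal(resolve_mode(730), "length")
  expect_equal(resolve_mode(731), "height")
  expect_equal(resolve_mode(180), "length")
})

test_that("height-age from mean stature transforms the point and CI", {
  c0 <- toy_combined()
  s <- summary_stature("stature", 55, mean_age_days = 50, mode = "length")
  est <- height_age_from_mean_stature(s, c0)
  expect_equal(est$point, 50)
  expect_true(is.na(est$se))

  s2 <- summary_stature("stature", 55, 54, 56, mean_age_days = 50, mode = "length")
  est2 <- height_age_from_mean_stature(s2, c0)
  # linear toy reference maps 1 cm to 10 d, so the CI is (40, 60) d and
  # SE = 20 / (2 * 1.959964)
  expect_equal(est2$point, 50)
  expect_equal(est2$ci_low, 40)
  expect_equal(est2$ci_high, 60)
  expect_equal(est2$se, 20 / (2 * 1.959964), tolerance = 1e-6)

  s3 <- summary_stature("stature", 49, mean_age_days = 50, mode = "length")
  expect_error(height_age_from_mean_stature(s3, c0), "underflow")
  expect_error(height_age_from_mean_stature(s3, c0), "mean")  # names the quantity
})

test_that("height-age from mean z back-calculates and agrees with the stature path", {
  c0 <- toy_combined()
  sz <- summary_stature("zscore", -2, mean_age_days = 50, mode = "length")
  expect_equal(height_age_from_mean_z(sz, c0)$point, 6)  # (50.6 - 50) / 0.1
  s0 <- summary_stature("zscore", 0, mean_age_days = 50, mode = "length")
  expect_equal(height_age_from_mean_z(s0, c0)$point, 50)

  # CI bounds transform monotonically and bracket the point
  sci <- summary_stature("zscore", -2, -2.2, -1.8, mean_age_days = 50,
                         mode = "length")
  eci <- height_age_from_mean_z(sci, c0)
  expect_lt(eci$ci_low, eci$point)
  expect_gt(eci$ci_high, eci$point)
  # independent bound oracle: brute-force lookup of each back-calculated bound
  lookup <- toy_lookup()
  expect_equal(eci$ci_low, oracle_nearest_age(lookup, 55 * (1 - 2.2 * 0.04)))
  expect_equal(eci$ci_high, oracle_nearest_age(lookup, 55 * (1 - 1.8 * 0.04)))

  # same lookup path as the corresponding mean stature, exactly
  # (z x t grid chosen so the back-calculated stature stays in R0's span)
  for (z in seq(-1.5, 0.4, by = 0.3)) {
    for (t in c(50, 70, 90)) {
      szt <- summary_stature("zscore", z, mean_age_days = t, mode = "length")
      yst <- summary_stature("stature", z_to_stature(z, t, toy_lookup()),
                             mean_age_days = t, mode = "length")
      expect_identical(height_age_from_mean_z(szt, c0)$point,
                       height_age_from_mean_stature(yst, c0)$point)
    }
  }
})

test_that("height-age is non-decreasing in mean stature and mean z", {
  c0 <- toy_combined()
  ha_of <- function(y) height_age_from_mean_stature(
    summary_stature("stature", y, mean_age_days = 50, mode = "length"), c0)$point
  ys <- seq(50, 60, by = 0.37)
  expect_true(all(diff(vapply(ys, ha_of, numeric(1))) >= 0))
  ha_z <- function(z) height_age_from_mean_z(
    summary_stature("zscore", z, mean_age_days = 50, mode = "length"), c0)$point
  zs <- seq(-2, 2, by = 0.2)
  expect_true(all(diff(vapply(zs, ha_z, numeric(1))) >= 0))
})

test_that("individual-level height-ages average to the cohort estimate", {
  ref <- toy_ref()
  # identity cohort: every child exactly on the median at its own age
  ages <- c(10, 25, 40, 60, 85)
  rec <- data.frame(age_days = ages, sex = rep(c("male", "female"), length.out = 5),
                    stature = 50 + 0.1 * ages, mode = "length")
  out <- height_age_from_individuals(rec, ref)
  expect_equal(out$per_record, ages)
  expect_equal(out$estimate$point, mean(ages))

  # single record: no SE, no CI
  one <- height_age_from_individuals(rec[1, ], ref)
  expect_true(is.na(one$estimate$se))
  expect_true(is.na(one$estimate$ci_low))

  # uniform z = -2 cohort agrees with the per-record brute-force oracle
  coh <- simulate_cohort(ref, 200, target_z_mean = -2, z_sd = 0,
                         age_range = c(50, 90), seed = 5)
  got <- height_age_from_individuals(coh, ref)
  lookup <- toy_lookup()
  oracle <- vapply(coh$stature, function(y) oracle_nearest_age(lookup, y),
                   numeric(1))
  expect_equal(got$per_record, oracle)
  expect_equal(got$estimate$point, mean(oracle))
  expect_equal(got$estimate$se, stats::sd(oracle) / sqrt(200))

  # out-of-range records are reported, not dropped
  bad <- rbind(rec, data.frame(age_days = 10, sex = "male", stature = 75,
                               mode = "length"))
  expect_error(height_age_from_individuals(bad, ref), "record 6")
})

test_that("distribution moments use central-moment estimators on the Table-2 scale", {
  m <- distribution_moments(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$median, 2)
  expect_equal(m$sd, 1)
  expect_equal(m$skewness, 0)
  expect_equal(m$kurtosis, 1.5)

  expect_warning(cm <- distribution_moments(rep(4, 10)), "zero variance")
  expect_equal(cm$sd, 0)
  expect_true(is.na(cm$skewness) && is.na(cm$kurtosis))
  expect_error(distribution_moments(1), "at least 2")

  # a large normal sample has non-excess kurtosis near 3
  set.seed(42)
  mn <- distribution_moments(stats::rnorm(1e5))
  expect_equal(mn$kurtosis, 3, tolerance = 0.1 / 3)
  expect_equal(mn$skewness, 0, tolerance = 0.05)
})
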