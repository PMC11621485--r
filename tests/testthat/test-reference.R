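test_that("load_reference reads both dialects and validates structure", {
  ref <- toy_ref()
  path <- withr::local_tempfile(fileext = ".csv")
  write_delimited(ref, path)
  back <- load_reference(path, "generic_delimited")
  expect_equal(back$M, ref$M)
  expect_equal(back$mode, ref$mode)

  # WHO layout: numeric sex codes, _agedays, lowercase lms, no mode column
  who <- data.frame(sex = rep(c(2, 1), each = 101),
                    "_agedays" = rep(0:100, 2),
                    l = 1, m = ref$M, s = ref$S, check.names = FALSE)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(who, path2, row.names = FALSE)
  back2 <- load_reference(path2, "who_lenanthro")
  expect_setequal(unique(back2$sex), c("male", "female"))
  expect_true(all(back2$mode == "length"))  # inferred: all ages < 731

  # tab-delimited accepted
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_delimited(ref, path3, sep = "\t")
  expect_equal(load_reference(path3, "generic_delimited")$M, ref$M)
})

test_that("load_reference rejects malformed tables with named errors", {
  ref <- as.data.frame(toy_ref())
  # missing S column
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ref[, c("sex", "age_days", "L", "M")], path, row.names = FALSE)
  expect_error(load_reference(path, "generic_delimited"), "lacks required column")

  # non-monotone median names the first offending age
  bad <- ref
  bad$M[bad$sex == "female" & bad$age_days == 2] <- bad$M[bad$age_days == 1][1] - 0.01
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(setNames(bad, tolower(names(bad))), path2, row.names = FALSE)
  expect_error(load_reference(path2, "generic_delimited"), "age 2")

  # L != 1 anywhere is unsupported
  badL <- ref
  badL$L[5] <- 0.5
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(setNames(badL, tolower(names(badL))), path3, row.names = FALSE)
  expect_error(load_reference(path3, "generic_delimited"), "L must equal 1")

  expect_error(load_reference(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("combine_sexes takes the sex-weighted mean of M and S", {
  two <- make_reference(max_age_days = 10, M0 = 64, a = 0.1, b = 0, k = 0,
                        cv_S = 0.04, sex_offset = 2, discontinuity = FALSE)
  # female M0 = 64, male M0 = 66
  expect_equal(combine_sexes(two, 0.5)$M[1], 65)
  expect_equal(combine_sexes(two, 0.25)$M[1], 65.5)
  f <- two[two$sex == "female", ]
  expect_equal(combine_sexes(two, 1)$M, f$M)
  expect_equal(combine_sexes(two, 1)$S, f$S)

  # ratio 0.5 equals the row-wise unweighted mean of the two sex tables
  m <- two[two$sex == "male", ]
  expect_equal(combine_sexes(two, 0.5)$M, (f$M + m$M) / 2, tolerance = 1e-12)

  single <- growth_reference(as.data.frame(f))
  expect_error(combine_sexes(single, 0.5), "both sexes")
  expect_error(combine_sexes(combine_sexes(two, 0.5), 0.5), "already")
  expect_error(combine_sexes(two, 1.2), "\\[0, 1\\]")
})

test_that("harmonize_mode shifts medians by 0.7 cm and is an involution", {
  ref <- who_like_ref()
  at731 <- function(r) r$M[r$sex == "female" & r$age_days == 731]
  at730 <- function(r) r$M[r$sex == "female" & r$age_days == 730]

  h <- harmonize_mode(ref, "height")
  expect_equal(at730(h), at730(ref) - 0.7)   # length row shifted down
  expect_equal(at731(h), at731(ref))          # height row unchanged
  expect_true(all(h$mode == "height"))

  l <- harmonize_mode(ref, "length")
  expect_equal(at731(l), at731(ref) + 0.7)
  expect_equal(at730(l), at730(ref))

  # involution up to mode flags: height then length restores medians exactly
  round_trip <- harmonize_mode(harmonize_mode(ref, "height"), "length")
  expect_equal(round_trip$M, harmonize_mode(ref, "length")$M)
  expect_equal(round_trip$M[ref$mode == "length"], ref$M[ref$mode == "length"])
})

test_that("median_at returns the exact row and range-errors outside the span", {
  c0 <- toy_combined()
  expect_equal(median_at(c0, 0)$M, 50)
  expect_equal(median_at(c0, 50)$M, 55)
  expect_equal(median_at(c0, 50)$S, 0.04)
  expect_error(median_at(c0, 200), "outside reference span")
  expect_error(median_at(toy_ref(), 50), "combined")
})

test_that("age_at_median is a nearest-row lookup with ties broken younger", {
  r <- toy_lookup()
  expect_equal(age_at_median(r, 55.0), 50)
  expect_equal(age_at_median(r, 55.04), oracle_nearest_age(r, 55.04))
  expect_equal(age_at_median(r, 55.04), 50)
  # 55.05 is equidistant between day 50 (55.0) and day 51 (55.1)
  expect_equal(age_at_median(r, 55.05), 50)
  # interpolated lookup returns the fractional day
  expect_equal(age_at_median(r, 55.05, interpolate = TRUE), 50.5)

  expect_error(age_at_median(r, 49.0), "underflow")
  expect_error(age_at_median(r, 61.0), "overflow")
  # within half the local median step the boundary rows are still assigned
  expect_equal(age_at_median(r, 49.96), 0)
  expect_equal(age_at_median(r, 60.04), 100)
  expect_error(age_at_median(toy_combined(), 55), NA)  # single-mode table is fine
})

test_that("inversion holds exhaustively and the lookup is monotone", {
  for (seed in 1:3) {
    r <- random_monotone_ref(seed = seed)
    # exhaustive inversion oracle over all table ages
    got <- vapply(r$age_days, function(a) age_at_median(r, median_at(r, a)$M),
                  numeric(1))
    expect_equal(got, as.numeric(r$age_days))
    # non-decreasing in stature
    set.seed(seed + 100)
    y <- sort(stats::runif(80, min(r$M), max(r$M)))
    ha <- vapply(y, function(yy) age_at_median(r, yy), numeric(1))
    expect_true(all(diff(ha) >= 0))
  }
})
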