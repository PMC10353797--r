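test_that("BMI classification follows the WHO Asian cutoffs", {
  expect_identical(
    as.character(classify_bmi(c(17, 18.5, 22.9, 23, 26, 27.5, 28))),
    c("underweight", "normal", "normal", "overweight", "overweight",
      "obese", "obese")
  )
  expect_error(classify_bmi(c(20, -1)), "positive")
  expect_error(classify_bmi(c(20, NA)), "finite")
  expect_error(classify_bmi("20"), "numeric")
  # classification is a monotone step function of bmi
  bmi <- sort(runif(500, 10, 40))
  codes <- as.integer(classify_bmi(bmi))
  expect_true(all(diff(codes) >= 0))
  # the boundary convention is configurable
  expect_identical(as.character(classify_bmi(23, cutoffs = c(18.5, 23.1, 27.5))),
                   "normal")
})

test_that("collapsing to three categories merges exactly the top two", {
  expect_identical(as.character(collapse_to_three("obese")), "overweight_obese")
  expect_identical(as.character(collapse_to_three("overweight")),
                   "overweight_obese")
  expect_identical(as.character(collapse_to_three("underweight")),
                   "underweight")
  expect_identical(as.character(collapse_to_three("normal")), "normal")
  out <- collapse_to_three(classify_bmi(seq(12, 40, by = 0.25)))
  expect_identical(levels(out), nutrition_levels())
  expect_setequal(as.character(unique(out)), nutrition_levels())
  # still monotone after composition
  expect_true(all(diff(as.integer(out)) >= 0))
  expect_error(collapse_to_three("chunky"), "unknown")
})

test_that("inclusion filters drop by flag then by missingness, in order", {
  d <- data.frame(
    id = 1:10,
    pregnant = c(TRUE, TRUE, rep(FALSE, 8)),
    recent_birth_within_2_months = c(TRUE, rep(FALSE, 9)),  # row 1 overlaps
    water = c(rep("protected", 7), NA, "protected", "protected"),
    toilet = c(rep("improved", 9), NA),
    stringsAsFactors = FALSE
  )
  res <- apply_inclusion_filters(d, covariates = c("water", "toilet"))
  expect_identical(nrow(res$kept), 6L)
  expect_identical(res$exclusion_log,
                   c(missing_toilet = 1L, missing_water = 1L, pregnant = 2L))
  # filtering is pure selection: survivors are untouched
  expect_identical(res$kept, d[c(3:7, 9), ])

  # a record missing several covariates is logged once, under the first
  # reason in the declared order
  d2 <- data.frame(water = NA_character_, toilet = NA_character_)
  r2 <- suppressWarnings(
    apply_inclusion_filters(d2, covariates = c("water", "toilet")))
  expect_identical(r2$exclusion_log, c(missing_water = 1L))
  r3 <- suppressWarnings(
    apply_inclusion_filters(d2, covariates = c("toilet", "water")))
  expect_identical(r3$exclusion_log, c(missing_toilet = 1L))

  # no flags, no missing -> identity
  clean <- data.frame(water = "protected")
  expect_identical(apply_inclusion_filters(clean)$kept, clean)
  expect_warning(apply_inclusion_filters(d2), "all records excluded")
})

test_that("pooled two-proportion test matches its closed form", {
  # equal proportions give z = 0, p = 1
  res <- two_proportion_test(30, 100, 60, 200)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)

  # independent closed-form recomputation
  res <- two_proportion_test(50, 100, 60, 100)
  pool <- 110 / 200
  z_exp <- (0.5 - 0.6) / sqrt(pool * (1 - pool) * (1 / 100 + 1 / 100))
  expect_equal(res$z, z_exp, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(z_exp)), tolerance = 1e-12)

  # symmetry: swapping groups flips the sign, p unchanged
  rev <- two_proportion_test(60, 100, 50, 100)
  expect_equal(rev$z, -res$z)
  expect_equal(rev$p_value, res$p_value)

  # the published underweight comparison is overwhelmingly significant
  expect_lt(two_proportion_test(2730, 14997, 1962, 16751)$p_value, 0.001)

  expect_warning(res0 <- two_proportion_test(0, 50, 0, 80), "degenerate")
  expect_equal(res0$p_value, 1)
})

test_that("descriptive table reproduces counts, percentages and p-values", {
  d1 <- data.frame(group = rep(c("a", "b", "c"), c(2730, 6155, 6112)))
  d2 <- data.frame(group = rep(c("a", "b", "c"), c(1962, 6294, 8495)))
  tab <- descriptive_table(d1, d2, "group")
  # published column: 18.2, 41.04, 40.76 (the last digit of the published
  # third entry is off by one unit from 6112/14997 = 40.754...%)
  expect_true(all(abs(tab$pct_year1 - c(18.2, 41.04, 40.76)) <= 0.011))
  expect_equal(sum(tab$count_year1), 14997L)
  expect_equal(sum(tab$pct_year1_raw), 100, tolerance = 1e-9)
  expect_true(all(tab$p_value < 0.001))
  # percentages survive rounding within half a unit in the last place
  expect_true(all(abs(tab$pct_year1 - tab$pct_year1_raw) <= 0.005 + 1e-12))

  # single-level variable: 100%, p = 1
  s <- descriptive_table(data.frame(v = "x"), data.frame(v = "x"), "v")
  expect_equal(s$pct_year1, 100)
  expect_equal(s$p_value, 1)

  # level absent in one round is reported with a zero count and a warning
  expect_warning(
    w <- descriptive_table(data.frame(v = c("x", "y")),
                           data.frame(v = c("x", "x")), "v"),
    "absent"
  )
  expect_identical(w$count_year2[w$level == "y"], 0L)
})

test_that("display rounding is half-up as in the published tables", {
  expect_equal(column_percentages(c(125, 875), digits = 1), c(12.5, 87.5))
  # 0.125% is an exact binary tie: half-up gives 0.13, banker's would give 0.12
  expect_equal(column_percentages(0.125, 100, digits = 2), 0.13)
})
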