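test_that("stage tabulation partitions records and validates sides", {
  rec <- rbind(expand_stage_counts("C57BL/6J", 14.0, 37, 0, 1),
               expand_stage_counts("C57BL/6J", 14.125, 79, 6, 29),
               expand_stage_counts("FVB/NJ", 13.875, 37, 0, 0))
  tab <- tabulate_stages(rec)
  c57_140 <- tab[tab$strain == "C57BL/6J" & tab$age_days == 14.0, ]
  expect_equal(unlist(c57_140[, c("n_unelevated", "n_unilateral",
                                  "n_elevated", "n_total")], use.names = FALSE),
               c(37, 0, 1, 38))
  c57_14125 <- tab[tab$strain == "C57BL/6J" & tab$age_days == 14.125, ]
  expect_equal(unlist(c57_14125[, c("n_unelevated", "n_unilateral",
                                    "n_elevated", "n_total")],
                      use.names = FALSE), c(79, 6, 29, 114))
  # empty strata are absent; totals conserve the input records
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$n_total), nrow(rec))
  bad <- rec; bad$side[bad$stage == "unilateral"][1] <- "none"
  expect_error(tabulate_stages(bad), "side")
})

test_that("integer percentages use half-away-from-zero rounding", {
  df <- data.frame(strain = "s", age_days = 14, sex = "all",
                   n_unelevated = c(37, 13, 0, 13),
                   n_unilateral = c(0, 0, 0, 0),
                   n_elevated = c(1, 51, 37, 51),
                   n_total = c(38, 64, 37, 64))
  pct <- stage_percentages(stage_table(df))
  expect_equal(pct$pct_unelevated, c(97, 20, 0, 20))
  expect_equal(pct$pct_elevated, c(3, 80, 100, 80))
  # fractions sum to 1 exactly before rounding; to 100 +/- 1 after
  set.seed(8)
  rand <- data.frame(strain = "r", age_days = 14, sex = "all",
                     n_unelevated = rpois(30, 20), n_unilateral = rpois(30, 5),
                     n_elevated = rpois(30, 15))
  rand$n_total <- rowSums(rand[, 4:6])
  rand <- rand[rand$n_total > 0, ]
  pr <- stage_percentages(stage_table(rand))
  expect_equal(pr$frac_unelevated + pr$frac_unilateral + pr$frac_elevated,
               rep(1, nrow(pr)))
  tot <- pr$pct_unelevated + pr$pct_unilateral + pr$pct_elevated
  expect_true(all(abs(tot - 100) <= 1))
  zero <- stage_table(data.frame(strain = "z", age_days = 14, sex = "all",
                                 n_unelevated = 0, n_unilateral = 0,
                                 n_elevated = 0, n_total = 0))
  expect_warning(stage_percentages(zero), "n_total = 0")
})

test_that("sex contrasts reproduce the reference Fisher results", {
  tab <- reference_stage_table()
  # C57BL/6J E14.25: all 30 males vs 21/34 females completed elevation
  res <- sex_contrast(tab, "C57BL/6J", 14.25, grouping = "elevated_vs_rest")
  expect_lte(res$p_value, 1e-4)
  # FVB/NJ E14.0: 33/38 females vs 24/48 males still unelevated
  res <- sex_contrast(tab, "FVB/NJ", 14.0, grouping = "unelevated_vs_rest")
  expect_lte(res$p_value, 5e-3)
  # identical sex distributions give p = 1; swapping sexes changes nothing
  same <- stage_table(data.frame(strain = "s", age_days = 14.25,
                                 sex = c("male", "female"),
                                 n_unelevated = c(5, 5), n_unilateral = c(2, 2),
                                 n_elevated = c(13, 13), n_total = c(20, 20)))
  expect_equal(sex_contrast(same, "s", 14.25)$p_value, 1)
  p_mf <- sex_contrast(tab, "C57BL/6J", 14.25)$p_value
  p_fm <- sex_contrast(tab, "C57BL/6J", 14.25,
                       sexes = c("female", "male"))$p_value
  expect_equal(p_mf, p_fm, tolerance = 1e-12)
})

test_that("elevation windows come from sampled ages only", {
  tab <- reference_stage_table()
  w <- elevation_window(tab, "C57BL/6J")
  expect_equal(w$window_start_age, 14.0)
  expect_equal(w$completion_age, 14.25)
  expect_equal(w$window_hours, 6)
  expect_equal(w$onset_age, 14.0)
  w <- elevation_window(tab, "FVB/NJ")
  expect_equal(w$window_start_age, 13.875)
  expect_equal(w$completion_age, 14.25)
  expect_equal(w$window_hours, 9)
  single <- stage_table(data.frame(strain = "x", age_days = 14, sex = "all",
                                   n_unelevated = 10, n_unilateral = 0,
                                   n_elevated = 0, n_total = 10))
  expect_error(elevation_window(single, "x"), "at least 2")
  # threshold never reached -> flagged incomplete
  low <- stage_table(data.frame(strain = "y", age_days = c(14, 14.25),
                                sex = "all", n_unelevated = c(10, 8),
                                n_unilateral = c(0, 1),
                                n_elevated = c(0, 1), n_total = c(10, 10)))
  expect_warning(w <- elevation_window(low, "y"), "never reached")
  expect_false(w$complete)
  expect_true(is.na(w$window_hours))
})

test_that("side preference is an exact binomial test on unilateral records", {
  rec <- expand_stage_counts("C57BL/6J", 14.125, 0, 6, 0)
  rec$side <- rep(c("left", "right"), each = 3)
  expect_equal(side_preference(rec)$p_value, 1)
  rec$side <- rep("left", 6)
  expect_equal(side_preference(rec)$p_value, 2 * 0.5^6, tolerance = 1e-12)
  rec7 <- expand_stage_counts("C57BL/6J", 14.125, 0, 7, 0)
  rec7$side <- rep(c("left", "right"), c(4, 3))
  expect_gt(side_preference(rec7)$p_value, 0.5)
  none <- expand_stage_counts("C57BL/6J", 14.125, 5, 0, 0)
  expect_true(side_preference(none)$degenerate)
})

test_that("sex contrast is calibrated on null cohorts", {
  # equal stage probabilities for both sexes: rejection at alpha = 0.05
  # should occur in about 5% of replicates
  st <- data.frame(strain = "C57BL/6J", sex = c("male", "female"),
                   age_days = 14.125, n_embryos = 150,
                   p_unelevated = 0.5, p_unilateral = 0.1, p_elevated = 0.4)
  d <- cohort_design(st)
  rej <- 0L
  for (i in 1:1000) {
    rec <- simulate_cohort(d, seed = 20000 + i)
    tb <- tabulate_stages(rec, by_sex = TRUE)
    if (sex_contrast(tb, "C57BL/6J", 14.125)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})
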