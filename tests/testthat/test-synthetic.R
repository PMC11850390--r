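strata_row <- function(n, p, strain = "C57BL/6J", sex = "unknown",
                       age = 14.125) {
  data.frame(strain = strain, sex = sex, age_days = age, n_embryos = n,
             p_unelevated = p[1], p_unilateral = p[2], p_elevated = p[3])
}

test_that("cohort simulation honours degenerate and stochastic designs", {
  rec <- simulate_cohort(cohort_design(strata_row(100, c(1, 0, 0))), seed = 1)
  expect_equal(nrow(rec), 100)
  expect_true(all(rec$stage == "bilat_unelevated"))
  expect_true(all(rec$side == "none"))

  rec <- simulate_cohort(cohort_design(strata_row(64, c(0, 0, 1))), seed = 1)
  expect_equal(nrow(rec), 64)
  expect_true(all(rec$stage == "bilat_elevated"))

  # stage fractions within 3 binomial SE of the design at n = 10000
  p <- c(0.2, 0.1, 0.7)
  rec <- simulate_cohort(cohort_design(strata_row(10000, p)), seed = 99)
  frac <- c(mean(rec$stage == "bilat_unelevated"),
            mean(rec$stage == "unilateral"),
            mean(rec$stage == "bilat_elevated"))
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(frac - p) <= 3 * se))
  expect_true(all(rec$side[rec$stage == "unilateral"] %in% c("left", "right")))
})

test_that("cohort simulation conserves counts and is reproducible", {
  st <- rbind(strata_row(40, c(0.5, 0.2, 0.3), sex = "male"),
              strata_row(25, c(0.3, 0.1, 0.6), sex = "female"),
              strata_row(0, c(1, 0, 0), age = 14.25))
  d <- cohort_design(st)
  rec1 <- simulate_cohort(d, seed = 7)
  rec2 <- simulate_cohort(d, seed = 7)
  expect_identical(rec1, rec2)
  expect_equal(nrow(rec1), 65)
  expect_equal(as.vector(table(rec1$sex)), c(25, 40))
  expect_error(cohort_design(strata_row(10, c(0.5, 0.2, 0.2))), "sum to 1")
  expect_error(cohort_design(strata_row(10, c(1, 0, 0), age = 12)), "13")
})

test_that("axial von Mises sampling has the designed limits and moments", {
  # kappa = 0: uniform on [0, 180), order parameter near 0 at large n
  a <- sample_axial_angles(45, 0, 10000, seed = 3)
  expect_true(all(a >= 0 & a < 180))
  expect_lt(order_parameter_global(a), 0.05)
  # near-point-mass limit
  a <- sample_axial_angles(30, 1e6, 500, seed = 4)
  expect_lt(max(axial_dist(a, 30)), 0.5)
  expect_gt(order_parameter_global(a), 0.999)
  # kappa = 2: sample S within 0.02 of the Bessel ratio at n = 10000
  a <- sample_axial_angles(120, 2, 10000, seed = 5)
  expect_lt(abs(order_parameter_global(a) - expected_order_parameter(2)), 0.02)
  expect_error(sample_axial_angles(0, -1, 10), "non-negative")
  expect_error(sample_axial_angles(0, 1, -5), "non-negative")
})

test_that("expected order parameter is the Bessel ratio I1/I0", {
  expect_equal(expected_order_parameter(0), 0)
  expect_equal(expected_order_parameter(Inf), 1)
  # frozen from independent numerical integration of the circular moments
  expect_equal(expected_order_parameter(2), 0.6977746580, tolerance = 1e-9)
  expect_true(all(diff(expected_order_parameter(c(0, .5, 1, 2, 5, 20))) > 0))
  expect_error(expected_order_parameter(-0.1), "non-negative")
})

test_that("sample order parameter converges to the closed form", {
  for (kappa in c(0, 1, 2, 5)) {
    a <- sample_axial_angles(77, kappa, 4000, seed = 100 + kappa)
    expect_lt(abs(order_parameter_global(a) - expected_order_parameter(kappa)),
              3 / sqrt(4000))
  }
})

test_that("section simulation: empty, deterministic, truth inside regions", {
  sp <- small_section_spec(nucleus_density = 0, seed = 2)
  sec <- simulate_section(sp)
  expect_equal(nrow(sec$truth), 0)
  expect_true(all(dim(sec$nuclear) == c(100, 120)))

  sp <- small_section_spec(seed = 5)
  s1 <- simulate_section(sp)
  s2 <- simulate_section(sp)
  expect_identical(s1$nuclear, s2$nuclear)
  expect_identical(s1$truth, s2$truth)
  expect_gt(nrow(s1$truth), 5)
  # every ground-truth centroid lies inside its declared region polygon
  for (i in seq_len(nrow(s1$truth))) {
    poly <- sp$regions[[s1$truth$region[i]]]
    expect_true(mgcv::in.out(rbind(poly, poly[1, ]),
                             cbind(s1$truth$x_um[i], s1$truth$y_um[i])))
  }
  # and the rasterized mask agrees at the centroid pixel
  nuc <- data.frame(nucleus_id = s1$truth$nucleus_id,
                    x_um = s1$truth$x_um, y_um = s1$truth$y_um)
  nuc <- assign_regions(nuc, s1$mask, s1$pixel_size_um)
  expect_equal(nuc$region, s1$truth$region)
})

test_that("overloaded placement fails naming the region", {
  sp <- small_section_spec(nucleus_density = 60, seed = 1)
  expect_error(simulate_section(sp), "region")
})

test_that("section TIFF round trip preserves channels and mask labels", {
  sec <- simulate_section(small_section_spec(seed = 9))
  img <- tempfile(fileext = ".tif"); msk <- tempfile(fileext = ".tif")
  tru <- tempfile(fileext = ".csv")
  write_section_tiff(sec, img, msk, tru)
  back <- read_section_tiff(img, msk, pixel_size_um = 1)
  expect_equal(dim(back$nuclear), dim(sec$nuclear))
  # 16-bit quantization error only
  expect_lt(max(abs(back$nuclear - sec$nuclear)), 1 / 65535)
  expect_lt(max(abs(back$marker - sec$marker)), 1 / 65535)
  expect_identical(back$mask, sec$mask)
  expect_equal(nrow(read.csv(tru)), nrow(sec$truth))
  unlink(c(img, msk, tru))
})
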