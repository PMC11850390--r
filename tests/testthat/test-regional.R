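mk_classified <- function(region, positive) {
  n <- length(region)
  data.frame(nucleus_id = sprintf("n%04d", seq_len(n)), x_um = seq_len(n),
             y_um = 1, area_um2 = 30, theta_deg = 0, aspect_ratio = 2,
             angle_defined = TRUE, marker_mean = 0.1, border = FALSE,
             region = region, positive = positive, stringsAsFactors = FALSE)
}

test_that("region assignment uses the centroid pixel and excludes epithelium", {
  mask <- matrix(0L, 10, 10)
  mask[1:5, ] <- 1L       # dorsal half = hinge (top rows)
  mask[6:10, 1:5] <- 3L   # buccal
  mask[6:10, 6:10] <- 2L  # lingual
  mask[10, ] <- 4L        # ventral epithelial strip
  nuc <- mk_classified(rep(NA_character_, 4), FALSE)
  nuc$x_um <- c(3, 3, 8, 3); nuc$y_um <- c(8, 2, 2, 0.5)
  out <- assign_regions(nuc, mask, pixel_size_um = 1)
  expect_equal(out$region, c("hinge", "buccal", "lingual", "excluded"))
  # outside the image bounds -> excluded with a warning
  nuc$y_um[1] <- 99
  expect_warning(out <- assign_regions(nuc, mask, pixel_size_um = 1),
                 "outside")
  expect_equal(out$region[1], "excluded")
})

test_that("region assignment round-trips the generator ground truth", {
  sec <- simulate_section(small_section_spec(seed = 3))
  nuc <- mk_classified(rep(NA_character_, nrow(sec$truth)), FALSE)
  nuc$x_um <- sec$truth$x_um; nuc$y_um <- sec$truth$y_um
  out <- assign_regions(nuc, sec$mask, sec$pixel_size_um)
  expect_equal(out$region, sec$truth$region)
})

test_that("proliferation deviations are exact differences from the mean", {
  nuc <- mk_classified(rep(c("hinge", "lingual", "buccal"), each = 10),
                       rep(c(FALSE, TRUE), 15))
  dev <- proliferation_deviation(nuc, "s")
  expect_equal(dev$deviation, rep(0, 3))
  # designed lingual excess with equal counts
  pos <- c(rep(c(TRUE, FALSE), c(2, 8)),    # hinge 0.2
           rep(c(TRUE, FALSE), c(5, 5)),    # lingual 0.5
           rep(c(TRUE, FALSE), c(2, 8)))    # buccal 0.2
  dev <- proliferation_deviation(mk_classified(
    rep(c("hinge", "lingual", "buccal"), each = 10), pos), "s")
  expect_equal(dev$section_mean, rep(0.3, 3))
  expect_equal(dev$deviation[dev$region == "lingual"], 0.2)
  expect_equal(dev$deviation[dev$region == "hinge"], -0.1)
  expect_equal(dev$n_positive[dev$region == "lingual"], 5)
  # empty region omitted with a warning; excluded nuclei never counted
  two <- mk_classified(rep(c("hinge", "lingual", "excluded"), each = 5),
                       rep(TRUE, 15))
  expect_warning(dev <- proliferation_deviation(two, "s"), "buccal")
  expect_setequal(dev$region, c("hinge", "lingual"))
  expect_equal(dev$n_basis, c(5, 5))
})

test_that("intensity deviations are exact differences from the pixel mean", {
  mask <- matrix(0L, 6, 9)
  mask[, 1:3] <- 1L; mask[, 4:6] <- 2L; mask[, 7:9] <- 3L  # equal areas
  img <- matrix(1, 6, 9)
  dev <- intensity_deviation(img, mask, "s")
  expect_equal(dev$deviation, rep(0, 3))
  cc <- 0.2
  img[mask == 1L] <- 2 * cc; img[mask == 2L] <- cc; img[mask == 3L] <- cc
  dev <- intensity_deviation(img, mask, "s")
  expect_equal(dev$deviation[dev$region == "hinge"], 2 * cc / 3,
               tolerance = 1e-12)
  expect_equal(dev$deviation[dev$region != "hinge"], rep(-cc / 3, 2),
               tolerance = 1e-12)
})

test_that("basis-weighted deviations sum to zero per section", {
  sec <- simulate_section(section_spec(seed = 29))
  labs <- segment_nuclei(sec$nuclear, sec$pixel_size_um)
  nuc <- nucleus_features(labs, sec$marker, sec$pixel_size_um)
  nuc <- classify_positive(assign_regions(nuc, sec$mask, sec$pixel_size_um))
  dk <- proliferation_deviation(nuc, "s")
  expect_lt(abs(sum(dk$deviation * dk$n_basis) / sum(dk$n_basis)), 1e-12)
  sec2 <- simulate_section(small_section_spec(marker_mode = "regional_field",
                                              seed = 30))
  dp <- intensity_deviation(sec2, section_id = "s")
  expect_lt(abs(sum(dp$deviation * dp$n_basis) / sum(dp$n_basis)), 1e-12)
})

test_that("intensity deviations are affine-stable under global offset/gain", {
  sec <- simulate_section(small_section_spec(marker_mode = "regional_field",
                                             seed = 31))
  d0 <- intensity_deviation(sec$marker, sec$mask, "s")
  # a global offset cancels exactly
  d_off <- intensity_deviation(sec$marker + 0.13, sec$mask, "s")
  expect_equal(d_off$deviation, d0$deviation, tolerance = 1e-12)
  # a global gain rescales deviations proportionally
  d_gain <- intensity_deviation(sec$marker * 2.5, sec$mask, "s")
  expect_equal(d_gain$deviation, 2.5 * d0$deviation, tolerance = 1e-12)
})

test_that("null cohorts show no systematic regional deviation", {
  sp <- small_section_spec(marker_mode = "regional_field",
                           region_intensity = c(hinge = 0.25, lingual = 0.25,
                                                buccal = 0.25),
                           nucleus_density = 0)
  devs <- do.call(rbind, lapply(1:10, function(i)
    intensity_deviation(simulate_section(sp, seed = 500 + i),
                        section_id = i)))
  for (r in c("hinge", "lingual", "buccal")) {
    v <- devs$deviation[devs$region == r]
    expect_lte(abs(mean(v)), 2 * sd(v) / sqrt(length(v)))
  }
})

test_that("group comparison is a Welch test on per-section values", {
  d <- data.frame(section_id = rep(1:8, each = 1),
                  region = "hinge", metric = "pmlc_intensity",
                  value = 0, section_mean = 0,
                  deviation = c(1, 2, 3, 4, 1, 2, 3, 4) / 10,
                  n_basis = 100, group = rep(c("A", "B"), each = 4))
  res <- group_compare(d, region = "hinge", groups = c("A", "B"))
  expect_equal(res$p_value, 1)
  expect_error(group_compare(d[-(1:3), ], region = "hinge",
                             groups = c("A", "B")), "at least 2")
  # region-vs-region contrast path
  d2 <- rbind(d, transform(d, region = "lingual", deviation = deviation + 1))
  res <- group_compare(d2, regions = c("lingual", "hinge"), group = "A")
  expect_lt(res$p_value, 0.01)
})

test_that("group comparison rejects at about the nominal rate under the null", {
  sp <- section_spec(width_um = 80, height_um = 60, pixel_size_um = 1,
                     nucleus_density = 0, marker_mode = "regional_field",
                     region_intensity = c(hinge = 0.25, lingual = 0.25,
                                          buccal = 0.25))
  rej <- 0L
  for (r in 1:100) {
    devs <- do.call(rbind, lapply(1:8, function(j) {
      d <- intensity_deviation(simulate_section(sp, seed = r * 31 + j),
                               section_id = j)
      d$group <- if (j <= 4) "A" else "B"
      d
    }))
    p <- group_compare(devs, region = "hinge", groups = c("A", "B"))$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 100, 0.01)
  expect_lte(rej / 100, 0.11)
})
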