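test_that("vesicle-area generator is seeded, positive and matches its moments", {
  a1 <- simulate_vesicle_areas(seed = 11)
  a2 <- simulate_vesicle_areas(seed = 11)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 121)
  expect_true(all(a1$area > 0))
  expect_equal(sum(a1$label_status == "OXT_pos"), 61)

  # degenerate distribution: sd 0 collapses to the mean
  deg <- simulate_vesicle_areas(sd_pos = 0, seed = 1)
  expect_true(all(deg$area[deg$label_status == "OXT_pos"] == 0.016))
  expect_error(simulate_vesicle_areas(sd_pos = -1, seed = 1), "sd")
  expect_error(simulate_vesicle_areas(n_pos = 1, seed = 1), ">= 2")

  # CLT bound: grand mean of labeled areas over 200 replicates stays within
  # 2 * (0.005 / sqrt(61)) of 0.016
  means <- vapply(1:200, function(s) {
    x <- simulate_vesicle_areas(seed = 1000 + s)
    mean(x$area[x$label_status == "OXT_pos"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.016), 2 * 0.005 / sqrt(61))
})

test_that("profile generator draws Bernoulli incidence at the requested rate", {
  expect_true(all(!simulate_profiles(20, 0, seed = 1)$contains_dcv))
  expect_true(all(simulate_profiles(20, 1, seed = 1)$contains_dcv))
  expect_error(simulate_profiles(20, 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(simulate_profiles(0, 0.5, seed = 1), ">= 1")

  # binomial simulation oracle: mean observed fraction over 500 replicates
  fr <- vapply(1:500, function(s) {
    mean(simulate_profiles(54, 0.26, seed = 2000 + s)$contains_dcv)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.26), 0.02)
})

test_that("section-score generator saturates at the bin extremes and is seeded", {
  regions0 <- tibble::tibble(region = "R", lambda = 0, n_sections = 10)
  s0 <- simulate_section_scores(regions0, n_animals = 2, seed = 5)
  expect_true(all(s0$score == 0))
  expect_true(all(compute_sdi(s0)$sdi == 0))

  regions_hi <- tibble::tibble(region = "R", lambda = 100, n_sections = 5)
  s3 <- simulate_section_scores(regions_hi, n_animals = 2, seed = 5)
  expect_true(all(s3$score == 3))
  expect_true(all(compute_sdi(s3)$sdi == 1))

  regions <- tibble::tibble(region = "R", lambda = 4, n_sections = 10)
  h1 <- table(simulate_section_scores(regions, n_animals = 3, seed = 7)$score)
  h2 <- table(simulate_section_scores(regions, n_animals = 3, seed = 7)$score)
  expect_identical(h1, h2)
  expect_error(
    simulate_section_scores(tibble::tibble(region = "R", lambda = -1,
                                           n_sections = 2), seed = 1),
    "lambda")
})

test_that("concordance generator encodes the linear structure and clips SDI", {
  cats <- tibble::tibble(category = c("a", "b"), intercept = c(0.2, 0.5),
                         slope = c(0, 0))
  flat <- simulate_concordance(cats, regions_per_category = 4, noise_sd = 0,
                               seed = 3)
  expect_equal(unique(flat$pooled_sdi[flat$category == "a"]), 0.2)
  expect_equal(unique(flat$pooled_sdi[flat$category == "b"]), 0.5)

  # noiseless known slope: downstream trend recovers it exactly
  cats2 <- tibble::tibble(category = c("a", "b"), intercept = c(0.1, 0.4),
                          slope = c(0.13, -0.04))
  sim2 <- simulate_concordance(cats2, regions_per_category = 6, noise_sd = 0,
                               seed = 4)
  tr <- suppressWarnings(estimate_trends(fit_interaction_model(sim2)))
  expect_equal(tr$trend[tr$category == "a"], 0.13, tolerance = 1e-9)
  expect_equal(tr$trend[tr$category == "b"], -0.04, tolerance = 1e-9)

  big <- simulate_concordance(
    tibble::tibble(category = "a", intercept = 0.9, slope = 0.2),
    regions_per_category = 200, noise_sd = 0.3, seed = 5)
  expect_true(all(big$pooled_sdi >= 0 & big$pooled_sdi <= 1))
  expect_true(all(big$receptor_score >= 1 & big$receptor_score <= 4))
  expect_error(simulate_concordance(cats[0, ], seed = 1), "at least one")

  # OLS simulation oracle: mean recovered trend near the generating slope
  cats3 <- tibble::tibble(
    category = c("thalamus", "hypothalamus", "cerebral_cortex"),
    intercept = c(0.1, 0.5, 0.05), slope = c(0.13, -0.04, 0.03))
  rec <- vapply(1:200, function(s) {
    sim <- simulate_concordance(cats3, regions_per_category = 5,
                                noise_sd = 0.05, seed = 3000 + s)
    tr <- estimate_trends(fit_interaction_model(sim))
    tr$trend[tr$category == "thalamus"]
  }, numeric(1))
  expect_lt(abs(mean(rec) - 0.13), 0.02)
})

test_that("puncta generator hits the requested expression probability", {
  none <- simulate_cell_puncta(p_express = 0, seed = 1)
  expect_true(all(none$puncta == 0))
  all_expr <- simulate_cell_puncta(p_express = 1, lambda = 5, seed = 1)
  expect_true(all(all_expr$puncta >= 1))
  p_hat <- vapply(1:200, function(s) {
    x <- simulate_cell_puncta(n_cells = 100, n_sections = 2,
                              p_express = 0.15, seed = 4000 + s)
    mean(x$puncta >= 1)
  }, numeric(1))
  se <- sqrt(0.15 * 0.85 / (200 * 200))
  expect_lt(abs(mean(p_hat) - 0.15), 2 * se + 0.005)
})

test_that("EM-image fixture renders measurable disks", {
  skip_if_not_installed("EBImage")
  blank <- simulate_em_image(numeric(0), pixel_size = 0.0008, seed = 1)
  expect_equal(nrow(measure_em_areas(blank$image, 0.0008)), 0)

  # one disk: pixel-counting oracle recovers the area within 5%
  one_area <- pi * 0.07^2
  one <- simulate_em_image(one_area, pixel_size = 0.0008, noise_sd = 0,
                           width_px = 256, height_px = 256, seed = 2)
  m <- measure_em_areas(one$image, 0.0008)
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$area_um2 - one_area) / one_area, 0.05)

  two <- simulate_em_image(c(0.002, 0.004), pixel_size = 0.0008, noise_sd = 5,
                           seed = 3)
  m2 <- measure_em_areas(two$image, 0.0008)
  expect_equal(nrow(m2), 2)
  # each measured component within 15% of a rendered truth area
  matched <- vapply(m2$area_um2, function(a) {
    min(abs(two$truth$area_um2 - a) / two$truth$area_um2)
  }, numeric(1))
  expect_true(all(matched < 0.15))

  expect_error(simulate_em_image(1e-7, pixel_size = 0.0008, seed = 1),
               "4 px")
  expect_error(simulate_em_image(0.01, pixel_size = 0.0008, width_px = 16,
                                 height_px = 16, seed = 1))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_vesicle_areas(seed = 5))
  invisible(simulate_profiles(10, 0.5, seed = 5))
  expect_identical(runif(1), before)
})
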