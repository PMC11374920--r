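make_sdi_table <- function() {
  tibble::tibble(region = c("BNST", "RE", "PVT", "Cg", "LonelyRegion"),
                 pooled_sdi = c(0.30, 0.46, 0.50, 0.05, 0.70))
}
make_receptor_table <- function() {
  tibble::tibble(
    region = c("BNSTa", "BNSTp", "RE", "PVT", "Cg", "OrphanNucleus"),
    score = c(3, 4, 2, 3, 3, 4))
}
make_mapping <- function() {
  tibble::tibble(
    region = c("BNST", "RE", "PVT", "Cg"),
    sdi_label = c("BNST", "RE", "PVT", "Cg"),
    receptor_labels = c("BNSTa; BNSTp", "RE", "PVT", "Cg"),
    category = c("striatum_pallidum", "thalamus", "thalamus",
                 "cerebral_cortex"))
}

test_that("harmonization averages subregions and audits every exclusion", {
  out <- harmonize_regions(make_sdi_table(), make_receptor_table(),
                           make_mapping())
  # subregion scores {3, 4} merge to 3.5 by the stated averaging rule
  expect_equal(out$receptor_score[out$region == "BNST"], 3.5)
  expect_true(all(out$included[out$region %in% make_mapping()$region]))

  lonely <- out[out$region == "LonelyRegion", ]
  expect_false(lonely$included)
  expect_equal(lonely$exclusion_reason, "no receptor counterpart")
  orphan <- out[out$region == "OrphanNucleus", ]
  expect_false(orphan$included)
  expect_equal(orphan$exclusion_reason, "no SDI counterpart")

  audit <- attr(out, "audit")
  # audit conserves rows on each side
  expect_equal(audit$n_matched + audit$n_sdi_unmatched,
               audit$n_sdi_input)
  expect_equal(audit$n_receptor_unmatched, 1)

  empty <- harmonize_regions(make_sdi_table(), make_receptor_table(),
                             make_mapping()[0, ])
  expect_equal(attr(empty, "audit")$n_matched, 0)

  bad <- make_mapping()
  bad$sdi_label[1] <- "Nowhere"
  expect_error(harmonize_regions(make_sdi_table(), make_receptor_table(),
                                 bad), "unknown labels: Nowhere")
})

test_that("region mapping round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "BNST:",
    "  sdi_label: BNST",
    "  receptor_labels: [BNSTa, BNSTp]",
    "  category: striatum_pallidum",
    "RE:",
    "  sdi_label: RE",
    "  receptor_labels: RE",
    "  category: thalamus"), path)
  map <- read_region_mapping(path)
  expect_equal(nrow(map), 2)
  expect_equal(map$receptor_labels[[1]], c("BNSTa", "BNSTp"))
  out <- harmonize_regions(make_sdi_table(), make_receptor_table(), map)
  expect_equal(out$receptor_score[out$region == "BNST"], 3.5)
})

test_that("the interaction model detects slope heterogeneity and not its absence", {
  # identical slopes, zero noise: the interaction explains nothing
  cats <- tibble::tibble(category = c("a", "b", "c"),
                         intercept = c(0.1, 0.3, 0.5), slope = 0.1)
  sim <- simulate_concordance(cats, regions_per_category = 5, noise_sd = 0,
                              seed = 61)
  fit <- suppressWarnings(fit_interaction_model(sim))
  aov_tab <- suppressWarnings(anova(fit$fit))
  expect_lt(aov_tab$`Sum Sq`[grep(":", rownames(aov_tab))], 1e-10)

  # one deviating slope, zero noise: overwhelming interaction evidence
  cats2 <- tibble::tibble(category = c("a", "b", "c", "d", "e"),
                          intercept = 0.3, slope = c(0.13, 0, 0, 0, 0))
  sim2 <- simulate_concordance(cats2, regions_per_category = 4, noise_sd = 0,
                               seed = 62)
  fit2 <- suppressWarnings(fit_interaction_model(sim2))
  expect_lt(fit2$interaction$p_value, 1e-6)
  expect_gt(fit2$interaction$statistic, 0)
  # df follow from the fitted design: categories minus one
  expect_equal(fit2$interaction$df1, 4)

  # a category holding a single region is named in the failure
  thin <- sim2[c(1:4, 5), ]
  expect_error(fit_interaction_model(thin), "b")
})

test_that("estimated trends equal per-category least-squares slopes", {
  cats <- tibble::tibble(
    category = c("thalamus", "hypothalamus", "cerebral_cortex"),
    intercept = c(0.1, 0.6, 0.02), slope = c(0.13, -0.04, 0.03))
  sim <- simulate_concordance(cats, regions_per_category = 6, noise_sd = 0.05,
                              seed = 63)
  fit <- fit_interaction_model(sim)
  trends <- estimate_trends(fit)
  for (cat_i in cats$category) {
    sub <- sim[sim$category == cat_i, ]
    direct <- unname(coef(lm(pooled_sdi ~ receptor_score, data = sub))[2])
    expect_equal(trends$trend[trends$category == cat_i], direct,
                 tolerance = 1e-10)
  }

  # invariance to the reference category of the interaction coding
  sim_releveled <- sim
  sim_releveled$category <- factor(sim_releveled$category,
                                   levels = c("thalamus", "cerebral_cortex",
                                              "hypothalamus"))
  fit2 <- fit_interaction_model(sim_releveled)
  trends2 <- estimate_trends(fit2)
  merged <- merge(trends, trends2, by = "category")
  expect_equal(merged$trend.x, merged$trend.y, tolerance = 1e-10)
  expect_equal(merged$se.x, merged$se.y, tolerance = 1e-10)
})

test_that("trends and SEs agree with emmeans::emtrends", {
  skip_if_not_installed("emmeans")
  cats <- tibble::tibble(
    category = c("thalamus", "hypothalamus", "striatum_pallidum"),
    intercept = c(0.1, 0.6, 0.35), slope = c(0.13, -0.04, -0.003))
  sim <- simulate_concordance(cats, regions_per_category = 7, noise_sd = 0.05,
                              seed = 64)
  fit <- fit_interaction_model(sim)
  trends <- estimate_trends(fit)
  em <- as.data.frame(emmeans::emtrends(fit$fit, "category",
                                        var = "receptor_score"))
  em <- em[match(trends$category, as.character(em$category)), ]
  expect_equal(trends$trend, em$receptor_score.trend, tolerance = 1e-10)
  expect_equal(trends$se, em$SE, tolerance = 1e-10)
  expect_equal(trends$conf_low, em$lower.CL, tolerance = 1e-8)
})

test_that("pure-noise responses yield trends centred on zero", {
  cats <- tibble::tibble(category = c("a", "b"), intercept = 0.4, slope = 0)
  reps <- purrr::map_dfr(1:200, function(s) {
    sim <- simulate_concordance(cats, regions_per_category = 6,
                                noise_sd = 0.05, seed = 7000 + s)
    estimate_trends(fit_interaction_model(sim))
  })
  by_cat <- dplyr::summarise(dplyr::group_by(reps, category),
                             m = mean(trend), mse = mean(se))
  expect_true(all(abs(by_cat$m) < 2 * by_cat$mse))
})

test_that("the transposed model orientation fits receptor on SDI", {
  cats <- tibble::tibble(category = c("a", "b"), intercept = c(0.1, 0.5),
                         slope = c(0.2, -0.1))
  sim <- simulate_concordance(cats, regions_per_category = 6, noise_sd = 0.03,
                              seed = 65)
  fit_t <- fit_interaction_model(sim, response = "receptor")
  expect_equal(fit_t$covariate, "pooled_sdi")
  trends_t <- estimate_trends(fit_t)
  direct <- unname(coef(lm(receptor_score ~ pooled_sdi,
                           data = sim[sim$category == "a", ]))[2])
  expect_equal(trends_t$trend[trends_t$category == "a"], direct,
               tolerance = 1e-10)
})
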