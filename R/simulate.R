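# Synthetic-data generators.  Every generator takes an explicit `seed`; with a
# fixed seed the returned table is bit-identical across runs.  Seeding is local
# (withr::local_seed), so generators never disturb the caller's RNG stream.

local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    withr::defer({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, envir = env)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Normal sampling truncated at zero by rejection.  The truncated mass is
# negligible for the vesicle-area defaults (0.016/0.005 = 3.2 sd,
# 0.004/0.002 = 2 sd) but induces a small positive bias on the mean; see the
# methods vignette.  sd = 0 gives the degenerate point mass at `mean`.
rnorm_pos <- function(n, mean, sd) {
  if (sd < 0) abort("`sd` must be >= 0.")
  if (mean <= 0) abort("`mean` must be > 0.")
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, mean, sd)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}

#' Simulate dense-cored vesicle area measurements
#'
#' Draws cross-sectional DCV areas for an oxytocin-labeled (OXT+) and an
#' unlabeled (OXT-) vesicle population from normal distributions truncated at
#' zero.  Defaults reproduce the two populations reported for the vole
#' paraventricular nucleus: large labeled vesicles (0.016 +/- 0.005 um^2,
#' n = 61) and small unlabeled vesicles (0.004 +/- 0.002 um^2, n = 60).
#'
#' A standard deviation of exactly 0 yields the degenerate distribution (all
#' areas equal to the mean); negative standard deviations are an error.
#'
#' @param n_pos,n_neg Number of labeled / unlabeled vesicles (>= 2).
#' @param mean_pos,sd_pos Mean and SD of labeled areas, um^2.
#' @param mean_neg,sd_neg Mean and SD of unlabeled areas, um^2.
#' @param region Region label attached to every row.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A tibble of vesicle measurements: `vesicle_id`, `profile_id`,
#'   `region`, `compartment`, `label_status` (`"OXT_pos"`/`"OXT_neg"`),
#'   `area` (um^2, all > 0).
#' @examples
#' areas <- simulate_vesicle_areas(seed = 1)
#' dplyr::count(areas, label_status)
#' @export
simulate_vesicle_areas <- function(n_pos = 61, mean_pos = 0.016, sd_pos = 0.005,
                                   n_neg = 60, mean_neg = 0.004, sd_neg = 0.002,
                                   region = "PVH", seed = NULL) {
  if (n_pos < 2 || n_neg < 2) abort("`n_pos` and `n_neg` must both be >= 2.")
  local_seed_if(seed)
  pos <- rnorm_pos(n_pos, mean_pos, sd_pos)
  neg <- rnorm_pos(n_neg, mean_neg, sd_neg)
  tibble(
    vesicle_id = paste0("v", seq_len(n_pos + n_neg)),
    profile_id = c(rep("labeled_soma", n_pos), rep("unlabeled_neuropil", n_neg)),
    region = region,
    compartment = c(rep("soma", n_pos), rep("terminal", n_neg)),
    label_status = c(rep("OXT_pos", n_pos), rep("OXT_neg", n_neg)),
    area = c(pos, neg)
  )
}

#' Simulate per-profile DCV presence records
#'
#' Each neuronal profile (one axon, dendrite or soma cross-section in one
#' ultrathin EM section) contains at least one supra-cutoff DCV with
#' probability `p_dcv`, independently across profiles.
#'
#' @param n_profiles Number of profiles (>= 1).
#' @param p_dcv Probability in \[0, 1\] that a profile contains a DCV.
#' @param region,compartment Labels attached to every row.
#' @param seed Integer seed.
#'
#' @return A tibble: `profile_id`, `region`, `compartment`,
#'   `contains_dcv` (logical).
#' @examples
#' simulate_profiles(48, 0.06, region = "LH", seed = 1)
#' @export
simulate_profiles <- function(n_profiles, p_dcv, region = "LH",
                              compartment = "axon", seed = NULL) {
  if (n_profiles < 1) abort("`n_profiles` must be >= 1.")
  if (p_dcv < 0 || p_dcv > 1) abort("`p_dcv` must lie in [0, 1].")
  local_seed_if(seed)
  tibble(
    profile_id = paste0(region, "_", compartment, "_", seq_len(n_profiles)),
    region = region,
    compartment = compartment,
    contains_dcv = rbinom(n_profiles, 1L, p_dcv) == 1L
  )
}

#' Simulate per-section ordinal staining scores
#'
#' For each animal x region x section, a latent cell count is drawn
#' Poisson(lambda) and mapped through the published scoring bins
#' (0; 1-6; 7-11; >= 12 cells) via [score_from_cell_count()].  An additive
#' `sex_effect` on lambda for females lets sex differences be injected.
#'
#' @param regions A data frame with columns `region`, `lambda`
#'   (mean cells per section, >= 0) and `n_sections` (sections spanned, >= 1).
#' @param n_animals Animals per sex.
#' @param sex_effect Additive shift of lambda for females (truncated at 0).
#' @param modality Modality label, `"cells"` or `"fibers"`.
#' @param seed Integer seed.
#'
#' @return A tibble of section scores: `animal`, `sex`, `region`,
#'   `section_index`, `modality`, `count`, `score`.
#' @examples
#' regions <- tibble::tibble(region = c("PVH", "SON"), lambda = c(20, 12),
#'                           n_sections = c(6, 4))
#' simulate_section_scores(regions, n_animals = 3, seed = 1)
#' @export
simulate_section_scores <- function(regions, n_animals = 3, sex_effect = 0,
                                    modality = "cells", seed = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("region", "lambda", "n_sections") %in% names(regions)))
  if (any(regions$lambda < 0)) abort("`lambda` must be >= 0.")
  if (any(regions$n_sections < 1)) abort("`n_sections` must be >= 1.")
  local_seed_if(seed)
  design <- tidyr::expand_grid(
    sex = c("M", "F"),
    animal_i = seq_len(n_animals),
    regions
  ) %>%
    mutate(animal = paste0(.data$sex, .data$animal_i)) %>%
    tidyr::uncount(.data$n_sections, .id = "section_index")
  lam <- pmax(design$lambda + ifelse(design$sex == "F", sex_effect, 0), 0)
  design %>%
    mutate(
      count = rpois(n(), lam),
      score = score_from_cell_count(.data$count),
      modality = modality
    ) %>%
    select("animal", "sex", "region", "section_index", "modality",
           "count", "score")
}

#' Simulate a region-level fiber/receptor concordance table
#'
#' Generates, per parent category, a set of regions with receptor scores drawn
#' on \[1, 4\] and pooled SDI values following a linear relationship
#' `sdi = intercept + slope * score + noise`, clipped to \[0, 1\].
#'
#' @param categories A data frame with columns `category`, `intercept` and
#'   `slope` (SDI units per receptor-score unit).
#' @param regions_per_category Regions generated per category.
#' @param noise_sd Gaussian noise SD on the SDI scale (>= 0).
#' @param score_range Receptor-score range, default `c(1, 4)` to match the
#'   published 1-4 transcript scores.
#' @param ordinal If `TRUE`, receptor scores are drawn on the integer grid
#'   of `score_range` instead of the continuous interval.
#' @param seed Integer seed.
#'
#' @return A tibble of [RegionConcordance]-shaped rows: `region`, `category`,
#'   `receptor_score`, `pooled_sdi`, `included` (all `TRUE`),
#'   `exclusion_reason` (all `""`).
#' @examples
#' cats <- tibble::tibble(category = c("thalamus", "cerebral_cortex"),
#'                        intercept = c(0.1, 0.05), slope = c(0.13, 0.03))
#' simulate_concordance(cats, regions_per_category = 5, seed = 1)
#' @export
simulate_concordance <- function(categories, regions_per_category = 5,
                                 noise_sd = 0.05, score_range = c(1, 4),
                                 ordinal = FALSE, seed = NULL) {
  stopifnot(is.data.frame(categories),
            all(c("category", "intercept", "slope") %in% names(categories)))
  if (nrow(categories) == 0) abort("`categories` must have at least one row.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  local_seed_if(seed)
  out <- tidyr::uncount(categories, regions_per_category, .id = "region_i") %>%
    mutate(region = paste0(.data$category, "_", .data$region_i))
  score <- if (ordinal) {
    sample(seq(score_range[1], score_range[2]), nrow(out), replace = TRUE)
  } else {
    runif(nrow(out), score_range[1], score_range[2])
  }
  out %>%
    mutate(
      receptor_score = score,
      pooled_sdi = pmin(pmax(.data$intercept + .data$slope * score +
                               rnorm(n(), 0, noise_sd), 0), 1),
      included = TRUE,
      exclusion_reason = ""
    ) %>%
    select("region", "category", "receptor_score", "pooled_sdi",
           "included", "exclusion_reason")
}

#' Simulate per-cell RNAScope puncta counts
#'
#' Cells express with probability `p_express` (Bernoulli); expressing cells
#' receive `1 + Poisson(lambda - 1)` puncta (a shifted Poisson, so every
#' expressing cell shows at least one punctum); non-expressing cells get 0.
#'
#' @param n_cells Cells per section.
#' @param n_sections Number of sections.
#' @param p_express Expression probability in \[0, 1\].
#' @param lambda Mean puncta per expressing cell (>= 1).
#' @param region,probe Labels attached to every row; `probe` is one of
#'   `"target"`, `"negative_control"`, `"positive_control"`.
#' @param seed Integer seed.
#'
#' @return A tibble: `cell_id`, `section_id`, `region`, `probe`, `puncta`.
#' @export
simulate_cell_puncta <- function(n_cells = 200, n_sections = 10,
                                 p_express = 0.15, lambda = 3.6,
                                 region = "AcbSh", probe = "target",
                                 seed = NULL) {
  if (p_express < 0 || p_express > 1) abort("`p_express` must lie in [0, 1].")
  if (lambda < 1) abort("`lambda` must be >= 1 (shifted Poisson).")
  local_seed_if(seed)
  total <- n_cells * n_sections
  expr <- rbinom(total, 1L, p_express) == 1L
  puncta <- integer(total)
  puncta[expr] <- 1L + rpois(sum(expr), lambda - 1)
  tibble(
    cell_id = paste0("c", seq_len(total)),
    section_id = paste0("s", rep(seq_len(n_sections), each = n_cells)),
    region = region,
    probe = probe,
    puncta = puncta
  )
}

#' Render a synthetic electron-micrograph fixture of dark disks
#'
#' Draws non-overlapping dark disks of the requested cross-sectional areas on
#' a brighter noisy background, emulating dense-cored vesicle profiles on a
#' uniform EM background.  Placement is by dart-throwing with at most 10^4
#' attempts per disk; exceeding the packing limit is an error.  The image is
#' 8-bit grayscale (integer matrix, 0-255).
#'
#' @param areas_um2 Vesicle areas in um^2 (all > 0); may be empty.
#' @param pixel_size um per pixel.  Must resolve the smallest disk at >= 4 px
#'   diameter.
#' @param noise_sd Gaussian background noise SD in grey levels.
#' @param width_px,height_px Image size in pixels.
#' @param fg,bg Disk and background grey levels.
#' @param seed Integer seed.
#'
#' @return A list with `image` (integer matrix, grey 0-255) and `truth`
#'   (tibble of `x_px`, `y_px`, `radius_px`, `area_um2` per disk).
#' @seealso [measure_em_areas()] for the companion measurement routine.
#' @export
simulate_em_image <- function(areas_um2, pixel_size = 0.0008, noise_sd = 0,
                              width_px = 256, height_px = 256,
                              fg = 50, bg = 200, seed = NULL) {
  if (length(areas_um2) > 0 && any(areas_um2 <= 0)) {
    abort("All `areas_um2` must be > 0.")
  }
  radius_px <- sqrt(areas_um2 / pi) / pixel_size
  if (length(radius_px) > 0 && min(radius_px) < 2) {
    abort("Smallest disk under 4 px diameter; decrease `pixel_size`.")
  }
  local_seed_if(seed)
  img <- matrix(bg, nrow = height_px, ncol = width_px)
  placed <- tibble(x_px = numeric(0), y_px = numeric(0),
                   radius_px = numeric(0), area_um2 = numeric(0))
  for (r in radius_px) {
    if (2 * r + 2 > min(width_px, height_px)) {
      abort("Disk larger than the image; increase the image size.")
    }
    ok <- FALSE
    for (attempt in seq_len(1e4)) {
      x <- runif(1, r + 1, width_px - r)
      y <- runif(1, r + 1, height_px - r)
      if (nrow(placed) == 0 ||
          all(sqrt((placed$x_px - x)^2 + (placed$y_px - y)^2) >
                placed$radius_px + r + 2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("Disk packing limit exceeded after 10^4 attempts.")
    placed <- bind_rows(placed, tibble(
      x_px = x, y_px = y, radius_px = r, area_um2 = pi * (r * pixel_size)^2
    ))
  }
  if (nrow(placed) > 0) {
    xs <- matrix(rep(seq_len(width_px), each = height_px), nrow = height_px)
    ys <- matrix(rep(seq_len(height_px), times = width_px), nrow = height_px)
    for (i in seq_len(nrow(placed))) {
      inside <- (xs - placed$x_px[i])^2 + (ys - placed$y_px[i])^2 <=
        placed$radius_px[i]^2
      img[inside] <- fg
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow = height_px)
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)),
                nrow = height_px)
  list(image = img, truth = placed)
}

#' Measure disk areas in a synthetic EM image
#'
#' Companion measurement routine for [simulate_em_image()]: global threshold
#' at the midpoint of the grey-level range, connected-components labelling,
#' and pixel counting converted to um^2.  Recovers each rendered area within
#' 15% for disks of at least 6 px diameter.
#'
#' @param image Integer grey-level matrix as returned by [simulate_em_image()].
#' @param pixel_size um per pixel used at rendering.
#' @param threshold Grey-level threshold; pixels strictly below it are
#'   foreground.  Default: midpoint of the observed grey range.
#'
#' @return A tibble with one row per connected component: `component`,
#'   `n_pixels`, `area_um2`.  Zero rows for a blank image.
#' @export
measure_em_areas <- function(image, pixel_size, threshold = NULL) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("measure_em_areas() requires the EBImage package.")
  }
  rng <- range(image)
  if (diff(rng) < 1e-8) {
    return(tibble(component = integer(0), n_pixels = integer(0),
                  area_um2 = numeric(0)))
  }
  threshold <- threshold %||% mean(rng)
  mask <- image < threshold
  labels <- EBImage::bwlabel(mask)
  sizes <- table(labels[labels > 0])
  tibble(
    component = as.integer(names(sizes)),
    n_pixels = as.integer(sizes),
    area_um2 = as.integer(sizes) * pixel_size^2
  )
}
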