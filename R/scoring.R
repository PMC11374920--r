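# Ordinal staining scores and the Staining Density Index (SDI).
#
# SDI = (3*N3 + 2*N2 + N1) / (3*NT), where N1..N3 count sections scored
# 1..3 and NT is the total number of sections the region spans, including
# sections with no stained cells or fibers.  SDI lies in [0, 1]: 0 when every
# section is empty, 1 when every section is maximally dense.

#' Map a cell count to its ordinal staining score
#'
#' Published bins: 0 cells -> 0; 1-6 cells -> 1; 6-12 cells -> 2; 12 or more
#' cells -> 3.  The published bin edges overlap at 6 and 12; this
#' implementation honors the explicit phrases "1-6 cells" and "12 or more",
#' i.e. 0 -> 0, 1-6 -> 1, 7-11 -> 2, >= 12 -> 3.
#'
#' @param count Non-negative integer cell count(s).
#' @return Integer score(s) in `0:3`.
#' @examples
#' score_from_cell_count(c(0, 3, 6, 7, 12))
#' @export
score_from_cell_count <- function(count) {
  if (any(is.na(count)) || any(count < 0) || any(count != floor(count))) {
    abort("`count` must be a non-negative integer.")
  }
  as.integer(cut(count, breaks = c(-0.5, 0.5, 6.5, 11.5, Inf),
                 labels = FALSE)) - 1L
}

#' Parse an ordinal fiber-density code
#'
#' Fiber density is recorded with the four-symbol alphabet `0`, `+`, `++`,
#' `+++` (from no axons encountered up to unquantifiably dense fibers).
#' Codes are whitespace-trimmed before matching; anything else is a parse
#' error that names the offending values and their positions.
#'
#' @param code Character vector of codes.
#' @return Integer score(s) in `0:3`.
#' @examples
#' parse_fiber_code(c("0", "+", "++ ", "+++"))
#' @export
parse_fiber_code <- function(code) {
  clean <- trimws(as.character(code))
  lookup <- c("0" = 0L, "+" = 1L, "++" = 2L, "+++" = 3L)
  score <- unname(lookup[clean])
  if (anyNA(score)) {
    bad <- which(is.na(score))
    abort(sprintf(
      "Unknown fiber code%s at position%s %s: %s",
      if (length(bad) > 1) "s" else "", if (length(bad) > 1) "s" else "",
      paste(bad, collapse = ", "),
      paste(sprintf('"%s"', code[bad]), collapse = ", ")
    ))
  }
  score
}

#' Compute the Staining Density Index per animal, region and modality
#'
#' Aggregates per-section ordinal scores into one SDI record per
#' animal x region x modality: `sdi = (3*N3 + 2*N2 + N1) / (3*NT)` where
#' `NT` is the number of sections spanned (zero-scored sections included).
#'
#' @param scores A data frame of section scores with columns `animal`,
#'   `region`, `modality`, `section_index`, `score` (in 0-3); a `sex` column
#'   is carried through if present.
#' @return A tibble with one row per animal x region x modality:
#'   `N1`, `N2`, `N3`, `NT` and `sdi` in \[0, 1\].
#' @examples
#' scores <- tibble::tibble(animal = "M1", region = "PVH", modality = "cells",
#'                          section_index = 1:4, score = c(1, 2, 3, 0))
#' compute_sdi(scores)  # (3 + 4 + 3) / 12 = 0.5... per formula
#' @export
compute_sdi <- function(scores) {
  stopifnot(is.data.frame(scores))
  needed <- c("animal", "region", "modality", "score")
  missing <- setdiff(needed, names(scores))
  if (length(missing) > 0) {
    abort(paste0("`scores` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(scores) == 0) abort("`scores` is empty (NT = 0).")
  if (!all(scores$score %in% 0:3)) abort("All scores must be in {0, 1, 2, 3}.")
  grp <- intersect(c("animal", "sex", "region", "modality"), names(scores))
  scores %>%
    group_by(across(all_of(grp))) %>%
    summarise(
      N1 = sum(.data$score == 1L),
      N2 = sum(.data$score == 2L),
      N3 = sum(.data$score == 3L),
      NT = n(),
      sdi = (3 * .data$N3 + 2 * .data$N2 + .data$N1) / (3 * .data$NT),
      .groups = "drop"
    )
}

#' Pool SDI values across animals
#'
#' Pools per-animal SDI records into one value per region (and modality, if
#' present) by the arithmetic mean.  A region contributes only through
#' animals in which it was examined (`NT > 0` recorded); regions missing
#' from an animal's table are treated as missing, not zero.
#'
#' @param sdi A tibble of SDI records as returned by [compute_sdi()].
#' @param method Pooling rule, `"mean"` (default) or `"median"`.
#' @return A tibble of `region` (and `modality`), `n_animals`, `pooled_sdi`.
#' @export
pool_sdi <- function(sdi, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(sdi), all(c("region", "sdi") %in% names(sdi)))
  fun <- if (method == "mean") mean else stats::median
  grp <- intersect(c("region", "modality"), names(sdi))
  sdi %>%
    group_by(across(all_of(grp))) %>%
    summarise(n_animals = n_distinct(.data$animal),
              pooled_sdi = fun(.data$sdi), .groups = "drop")
}

#' Classify regions into density tertiles
#'
#' Splits pooled SDI values at their empirical 33.3 and 66.7 percentiles
#' (linear-interpolation quantiles) into `"dense"`, `"sparse"` and
#' `"very sparse"` classes.  Ties at a boundary go to the denser class.  The
#' boundaries are attached as the `"boundaries"` attribute and returned as
#' columns.  If all SDIs are equal the partition is degenerate (every region
#' `"dense"`) and a warning is emitted.
#'
#' @param pooled A data frame with columns `region` and `pooled_sdi`
#'   (>= 3 rows).
#' @return The input tibble with `tertile` (factor, densest first),
#'   `tertile_lower` and `tertile_upper` columns added.
#' @export
classify_tertiles <- function(pooled) {
  stopifnot(is.data.frame(pooled),
            all(c("region", "pooled_sdi") %in% names(pooled)))
  if (nrow(pooled) < 3) abort("Tertile classification needs >= 3 regions.")
  qs <- quantile(pooled$pooled_sdi, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  if (diff(range(pooled$pooled_sdi)) < .Machine$double.eps) {
    warn("All pooled SDIs are equal; every region falls in one class.")
  }
  out <- pooled %>%
    mutate(
      tertile = factor(
        case_when(
          .data$pooled_sdi >= qs[2] ~ "dense",
          .data$pooled_sdi >= qs[1] ~ "sparse",
          TRUE ~ "very sparse"
        ),
        levels = c("dense", "sparse", "very sparse")
      ),
      tertile_lower = qs[1],
      tertile_upper = qs[2]
    )
  attr(out, "boundaries") <- qs
  out
}

# Closed-form Welch two-sample statistic; returns t, Welch-Satterthwaite df
# and the two-sided p.  Needed instead of t.test() so the zero-variance edge
# cases are reportable rather than an error.
welch_stats <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) {
      return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                  note = "t undefined: zero variance in both groups, equal means"))
    }
    return(list(t = sign(m1 - m2) * Inf, df = NA_real_, p = 0,
                note = "zero variance in both groups, unequal means"))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), note = "")
}

#' Screen regions for sex differences in SDI
#'
#' Per region (and modality), compares male and female per-animal SDI values
#' with Welch's unequal-variance t-test.  Regions with fewer than `min_obs`
#' values in either sex are not tested but are kept in the output with
#' `included = FALSE` and the reason, so nothing is silently dropped.  The
#' convention for the sign follows the female-minus-male difference:
#' positive t means higher female SDI.
#'
#' @param sdi A tibble of SDI records (needs `sex` with levels `"M"`/`"F"`).
#' @param min_obs Minimum observations per sex for a region to be tested.
#' @param adjust If `TRUE`, append Benjamini-Hochberg `q_value`s across the
#'   tested regions.  Off by default: the screen is exploratory and raw
#'   two-sided p-values are reported.
#' @return A tibble per region: group sizes, means and SDs per sex, Welch
#'   `t`, `df`, `p_value`, `included`, `exclusion_reason` (and `q_value`
#'   when `adjust = TRUE`).
#' @export
sex_difference_screen <- function(sdi, min_obs = 2, adjust = FALSE) {
  stopifnot(is.data.frame(sdi),
            all(c("sex", "region", "sdi") %in% names(sdi)))
  grp <- intersect(c("region", "modality"), names(sdi))
  out <- sdi %>%
    group_by(across(all_of(grp))) %>%
    summarise(
      n_m = sum(.data$sex == "M"),
      n_f = sum(.data$sex == "F"),
      mean_m = mean(.data$sdi[.data$sex == "M"]),
      sd_m = sd(.data$sdi[.data$sex == "M"]),
      mean_f = mean(.data$sdi[.data$sex == "F"]),
      sd_f = sd(.data$sdi[.data$sex == "F"]),
      stats = list(if (.data$n_m[1] >= min_obs && .data$n_f[1] >= min_obs) {
        welch_stats(.data$sdi[.data$sex == "F"], .data$sdi[.data$sex == "M"])
      } else {
        list(t = NA_real_, df = NA_real_, p = NA_real_, note = "")
      }),
      .groups = "drop"
    ) %>%
    mutate(
      included = .data$n_m >= min_obs & .data$n_f >= min_obs,
      t = purrr::map_dbl(.data$stats, "t"),
      df = purrr::map_dbl(.data$stats, "df"),
      p_value = purrr::map_dbl(.data$stats, "p"),
      exclusion_reason = case_when(
        !.data$included ~ sprintf("fewer than %d observations in one sex",
                                  min_obs),
        purrr::map_chr(.data$stats, "note") != "" ~
          purrr::map_chr(.data$stats, "note"),
        TRUE ~ ""
      )
    ) %>%
    select(-"stats")
  if (adjust) {
    out <- out %>% mutate(q_value = p.adjust(.data$p_value, method = "BH"))
  }
  out
}
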