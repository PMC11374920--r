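# RNAScope puncta summaries: percent of cells expressing the transcript,
# puncta density per cell, and control-probe checks.

#' Percent of cells expressing, per region
#'
#' A cell "expresses" when it carries at least `min_puncta` puncta (default
#' 1).  The percentage is computed per section and summarized as
#' mean +/- SD across sections, the convention behind figures such as
#' "15.4% +/- 6.9 of cells".
#'
#' @param cells A data frame of per-cell counts with columns `section_id`,
#'   `region`, `puncta` (and optionally `probe`, carried into the grouping).
#' @param min_puncta Minimum puncta for a cell to count as expressing.
#' @return A tibble per region (x probe): `n_sections`, `n_cells`,
#'   `percent_mean`, `percent_sd` (NA with a single section).
#' @examples
#' cells <- simulate_cell_puncta(p_express = 0.154, seed = 4)
#' percent_expressing(cells)
#' @export
percent_expressing <- function(cells, min_puncta = 1) {
  stopifnot(is.data.frame(cells),
            all(c("section_id", "region", "puncta") %in% names(cells)))
  if (nrow(cells) == 0) abort("`cells` is empty.")
  if (any(cells$puncta < 0)) abort("Puncta counts must be >= 0.")
  grp <- intersect(c("region", "probe"), names(cells))
  cells %>%
    group_by(across(all_of(c(grp, "section_id")))) %>%
    summarise(pct = 100 * mean(.data$puncta >= min_puncta),
              n_cells = n(), .groups = "drop") %>%
    group_by(across(all_of(grp))) %>%
    summarise(
      n_sections = n(),
      n_cells = sum(.data$n_cells),
      percent_mean = mean(.data$pct),
      percent_sd = sd(.data$pct),
      .groups = "drop"
    )
}

#' Puncta density per cell
#'
#' Mean +/- SD of puncta counts per cell, per region (x probe), either among
#' expressing cells only (default, matching counts "per Oxtr-expressing
#' cell") or over all cells; the choice is recorded in the output because
#' the two conventions differ whenever zero-count cells are present.
#'
#' @param cells A data frame of per-cell counts (columns `region`, `puncta`).
#' @param among `"expressing"` (cells with `puncta >= min_puncta`) or
#'   `"all"`.
#' @param min_puncta Expression threshold used when `among = "expressing"`.
#' @return A tibble per region (x probe): `among`, `n_cells`,
#'   `mean_puncta`, `sd_puncta`.
#' @examples
#' cells <- simulate_cell_puncta(seed = 4)
#' puncta_density(cells, among = "expressing")
#' puncta_density(cells, among = "all")
#' @export
puncta_density <- function(cells, among = c("expressing", "all"),
                           min_puncta = 1) {
  among <- match.arg(among)
  stopifnot(is.data.frame(cells),
            all(c("region", "puncta") %in% names(cells)))
  sel <- if (among == "expressing") {
    filter(cells, .data$puncta >= min_puncta)
  } else {
    cells
  }
  if (nrow(sel) == 0) abort("Empty cell selection.")
  grp <- intersect(c("region", "probe"), names(cells))
  sel %>%
    group_by(across(all_of(grp))) %>%
    summarise(
      among = among,
      n_cells = n(),
      mean_puncta = mean(.data$puncta),
      sd_puncta = sd(.data$puncta),
      .groups = "drop"
    )
}

#' Check RNAScope control probes
#'
#' The negative-control probe passes when its median puncta per cell is at
#' most `neg_median_max` (default 0, operationalizing "no specific
#' labeling"); the positive-control probe passes when its mean puncta per
#' cell exceeds `pos_mean_min` (default 15).  A missing control group is
#' reported as `"not assessed"` rather than failed.
#'
#' @param cells A data frame with columns `probe` (values
#'   `"negative_control"` / `"positive_control"`, other probes ignored) and
#'   `puncta`.
#' @param neg_median_max Maximum allowed median for the negative control.
#' @param pos_mean_min Minimum required mean for the positive control.
#' @return A tibble with one row per control: `probe`, `n_cells`,
#'   `statistic` (median or mean), `criterion`, `status`
#'   (`"pass"`/`"fail"`/`"not assessed"`).
#' @export
control_check <- function(cells, neg_median_max = 0, pos_mean_min = 15) {
  stopifnot(is.data.frame(cells),
            all(c("probe", "puncta") %in% names(cells)))
  neg <- cells$puncta[cells$probe == "negative_control"]
  pos <- cells$puncta[cells$probe == "positive_control"]
  bind_rows(
    tibble(
      probe = "negative_control",
      n_cells = length(neg),
      statistic = if (length(neg)) stats::median(neg) else NA_real_,
      criterion = sprintf("median <= %g", neg_median_max),
      status = if (!length(neg)) "not assessed"
               else if (stats::median(neg) <= neg_median_max) "pass"
               else "fail"
    ),
    tibble(
      probe = "positive_control",
      n_cells = length(pos),
      statistic = if (length(pos)) mean(pos) else NA_real_,
      criterion = sprintf("mean > %g", pos_mean_min),
      status = if (!length(pos)) "not assessed"
               else if (mean(pos) > pos_mean_min) "pass"
               else "fail"
    )
  )
}
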