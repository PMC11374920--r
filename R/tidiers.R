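# broom-style tidiers for the package's fitted objects.

#' Tidy a DCV cutoff object
#'
#' Returns the density curves on the evaluation grid in long format, one row
#' per grid point and population.
#'
#' @param x A `dcv_cutoff` object.
#' @param ... Unused.
#' @return A tibble with `area`, `population` (`"OXT_pos"`/`"OXT_neg"`) and
#'   `density`.
#' @export
tidy.dcv_cutoff <- function(x, ...) {
  x$curves %>%
    tidyr::pivot_longer(c("density_pos", "density_neg"),
                        names_to = "population", values_to = "density") %>%
    mutate(population = ifelse(.data$population == "density_pos",
                               "OXT_pos", "OXT_neg"))
}

#' Glance at a DCV cutoff object
#'
#' @param x A `dcv_cutoff` object.
#' @param ... Unused.
#' @return A one-row tibble: `cutoff_area`, `frac_labeled_below`,
#'   `flag_subcutoff`, `bw_pos`, `bw_neg`, `n_pos`, `n_neg`, `n_crossings`.
#' @export
glance.dcv_cutoff <- function(x, ...) {
  tibble(
    cutoff_area = x$cutoff_area,
    frac_labeled_below = x$frac_labeled_below,
    flag_subcutoff = x$flag_subcutoff,
    bw_pos = unname(x$bandwidths["pos"]),
    bw_neg = unname(x$bandwidths["neg"]),
    n_pos = x$n_pos,
    n_neg = x$n_neg,
    n_crossings = length(x$crossings)
  )
}

#' Tidy a fiber-receptor interaction fit
#'
#' Coefficient table of the underlying linear model.
#'
#' @param x A `concordance_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.concordance_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p_value = co[, "Pr(>|t|)"]
  )
}

#' Glance at a fiber-receptor interaction fit
#'
#' @param x A `concordance_fit`.
#' @param ... Unused.
#' @return A one-row tibble: interaction `statistic` (F), `df1`, `df2`,
#'   `p_value`, plus `r_squared`, `n`, `orientation`, `reference`.
#' @export
glance.concordance_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    statistic = x$interaction$statistic,
    df1 = x$interaction$df1,
    df2 = x$interaction$df2,
    p_value = x$interaction$p_value,
    r_squared = s$r.squared,
    n = nrow(x$data),
    orientation = x$orientation,
    reference = x$reference
  )
}
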