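# ggplot2 figures for the pipeline's result types.

#' Plot the DCV area densities and cutoff
#'
#' Both kernel density curves with the estimated intersection cutoff as a
#' dashed vertical line — the standard figure accompanying a size criterion.
#'
#' @param object A `dcv_cutoff` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcv_cutoff <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(.data$area, .data$density,
                                 colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff_area, linetype = "dashed") +
    ggplot2::labs(
      x = expression("DCV area (" * mu * m^2 * ")"), y = "density",
      colour = NULL,
      title = sprintf("DCV size cutoff: %.4g um^2 (%.1f%% labeled at or below)",
                      object$cutoff_area, 100 * object$frac_labeled_below)
    ) +
    ggplot2::theme_minimal()
}

#' Plot fiber-receptor concordance by category
#'
#' Scatter of the modelled response against the covariate, with per-category
#' least-squares lines and confidence bands.
#'
#' @param object A `concordance_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concordance_fit <- function(object, ...) {
  if (object$orientation == "sdi") {
    aes <- ggplot2::aes(.data$receptor_score, .data$pooled_sdi,
                        colour = .data$category, fill = .data$category)
    labs <- ggplot2::labs(x = "receptor transcript score (1-4)",
                          y = "pooled fiber SDI")
  } else {
    aes <- ggplot2::aes(.data$pooled_sdi, .data$receptor_score,
                        colour = .data$category, fill = .data$category)
    labs <- ggplot2::labs(x = "pooled fiber SDI",
                          y = "receptor transcript score (1-4)")
  }
  ggplot2::ggplot(object$data, aes) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, alpha = 0.15) +
    labs +
    ggplot2::theme_minimal()
}

#' Plot regions ranked by pooled SDI with tertile classes
#'
#' @param tertiles Output of [classify_tertiles()].
#' @return A ggplot.
#' @export
plot_sdi_tertiles <- function(tertiles) {
  stopifnot(is.data.frame(tertiles),
            all(c("region", "pooled_sdi", "tertile") %in% names(tertiles)))
  tertiles %>%
    mutate(region = stats::reorder(.data$region, .data$pooled_sdi)) %>%
    ggplot2::ggplot(ggplot2::aes(.data$pooled_sdi, .data$region,
                                 fill = .data$tertile)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "pooled SDI", y = NULL, fill = "density class") +
    ggplot2::theme_minimal()
}

#' Volcano plot of the sex-difference screen
#'
#' Welch t statistic against -log10(p) per region; positive t means higher
#' female SDI.  Untested (excluded) regions are omitted from the panel.
#'
#' @param screen Output of [sex_difference_screen()].
#' @param alpha Significance highlight level.
#' @return A ggplot.
#' @export
plot_sex_screen <- function(screen, alpha = 0.05) {
  stopifnot(is.data.frame(screen),
            all(c("region", "t", "p_value") %in% names(screen)))
  screen %>%
    filter(.data$included, is.finite(.data$t)) %>%
    mutate(signif = .data$p_value < alpha) %>%
    ggplot2::ggplot(ggplot2::aes(.data$t, -log10(.data$p_value),
                                 colour = .data$signif)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = "Welch t (female - male)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
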