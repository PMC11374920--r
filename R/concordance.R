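# Region-wise concordance between oxytocin fiber density (pooled SDI) and
# receptor-transcript scores: label harmonization against an external 1-4
# scored receptor dataset, an interaction linear model, and per-category
# estimated linear trends extracted as contrasts.

#' Harmonize region labels between an SDI table and a receptor-score table
#'
#' Joins the two datasets through a user-supplied mapping.  When one mapped
#' region corresponds to several receptor subregions (e.g. a nucleus the
#' receptor atlas splits further), the receptor score is the arithmetic mean
#' over the subregions.  Regions on either side with no counterpart are kept
#' in the output with `included = FALSE` and an explicit reason — exclusion
#' is auditable, never silent.  A matched/excluded audit per side is attached
#' as the `"audit"` attribute.
#'
#' @param sdi_table Data frame with columns `region`, `pooled_sdi`.
#' @param receptor_table Data frame with columns `region`, `score`.
#' @param mapping Data frame with one row per harmonized region: columns
#'   `region` (output label), `sdi_label` (label in `sdi_table`),
#'   `receptor_labels` (character; several labels separated by `";"`, or a
#'   list-column), `category` (parent anatomical category).  See
#'   [read_region_mapping()] for the YAML format.
#' @return A tibble of region-concordance rows: `region`, `category`,
#'   `pooled_sdi`, `receptor_score`, `included`, `exclusion_reason`; with
#'   attribute `"audit"` (named list of matched/excluded counts per side).
#' @export
harmonize_regions <- function(sdi_table, receptor_table, mapping) {
  stopifnot(is.data.frame(sdi_table),
            all(c("region", "pooled_sdi") %in% names(sdi_table)),
            is.data.frame(receptor_table),
            all(c("region", "score") %in% names(receptor_table)))
  if (nrow(mapping) == 0) {
    out <- tibble(region = character(0), category = character(0),
                  pooled_sdi = numeric(0), receptor_score = numeric(0),
                  included = logical(0), exclusion_reason = character(0))
    attr(out, "audit") <- list(n_sdi_input = nrow(sdi_table),
                               n_receptor_input = nrow(receptor_table),
                               n_matched = 0L,
                               n_sdi_unmatched = nrow(sdi_table),
                               n_receptor_unmatched = nrow(receptor_table))
    return(out)
  }
  stopifnot(all(c("region", "sdi_label", "receptor_labels", "category") %in%
                  names(mapping)))
  mapping <- as_tibble(mapping)
  if (!is.list(mapping$receptor_labels)) {
    mapping$receptor_labels <- strsplit(mapping$receptor_labels, ";\\s*")
  }
  unknown_sdi <- setdiff(mapping$sdi_label, sdi_table$region)
  unknown_rec <- setdiff(unlist(mapping$receptor_labels),
                         receptor_table$region)
  if (length(unknown_sdi) > 0 || length(unknown_rec) > 0) {
    abort(paste0("Mapping references unknown labels: ",
                 paste(c(unknown_sdi, unknown_rec), collapse = ", ")))
  }
  matched <- mapping %>%
    mutate(
      pooled_sdi = sdi_table$pooled_sdi[match(.data$sdi_label,
                                              sdi_table$region)],
      # stated averaging rule: mean receptor score across mapped subregions
      receptor_score = purrr::map_dbl(.data$receptor_labels, function(labs) {
        mean(receptor_table$score[match(labs, receptor_table$region)])
      }),
      included = TRUE,
      exclusion_reason = ""
    ) %>%
    select("region", "category", "pooled_sdi", "receptor_score",
           "included", "exclusion_reason")
  sdi_left <- setdiff(sdi_table$region, mapping$sdi_label)
  rec_left <- setdiff(receptor_table$region, unlist(mapping$receptor_labels))
  excluded <- bind_rows(
    tibble(region = sdi_left, category = NA_character_,
           pooled_sdi = sdi_table$pooled_sdi[match(sdi_left,
                                                   sdi_table$region)],
           receptor_score = NA_real_, included = FALSE,
           exclusion_reason = "no receptor counterpart"),
    tibble(region = rec_left, category = NA_character_,
           pooled_sdi = NA_real_,
           receptor_score = receptor_table$score[match(rec_left,
                                                       receptor_table$region)],
           included = FALSE, exclusion_reason = "no SDI counterpart")
  )
  out <- bind_rows(matched, excluded)
  attr(out, "audit") <- list(
    n_sdi_input = nrow(sdi_table),
    n_receptor_input = nrow(receptor_table),
    n_matched = nrow(matched),
    n_sdi_unmatched = length(sdi_left),
    n_receptor_unmatched = length(rec_left)
  )
  out
}

#' Read a region-label mapping from YAML
#'
#' YAML format: a map of output region -> `{sdi_label, receptor_labels,
#' category}` where `receptor_labels` is a scalar or sequence.
#'
#' @param path Path to the YAML file.
#' @return A mapping tibble usable by [harmonize_regions()].
#' @export
read_region_mapping <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap_dfr(raw, function(entry, name) {
    tibble(region = name,
           sdi_label = entry$sdi_label,
           receptor_labels = list(as.character(entry$receptor_labels)),
           category = entry$category)
  })
}

#' Fit the fiber-receptor interaction linear model
#'
#' Ordinary least squares of `response ~ covariate * category` (full
#' interaction) on the included concordance rows.  Default orientation
#' regresses pooled SDI on receptor score; `response = "receptor"` fits the
#' transpose.  The hindbrain category is dropped by default, keeping the five
#' parent categories of the trend analysis; set `include_hindbrain = TRUE`
#' to keep it.
#'
#' The interaction test is the F-test of the interaction term from the
#' sequential ANOVA table; its degrees of freedom follow from the fitted
#' design (number of categories minus one, by residual df) and are reported
#' as such.
#'
#' @param concordance A region-concordance tibble (as from
#'   [harmonize_regions()] or [simulate_concordance()]); only rows with
#'   `included = TRUE` are used.
#' @param response `"sdi"` (default) or `"receptor"`: which variable is
#'   modelled as the response.
#' @param include_hindbrain Keep hindbrain rows in the fit (default FALSE).
#' @return An object of class `concordance_fit`: list with the `lm` fit
#'   (`fit`), `orientation`, `reference` category, `interaction` (one-row
#'   tibble: `df1`, `df2`, `statistic`, `p_value`) and the modelling `data`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_interaction_model <- function(concordance, response = c("sdi", "receptor"),
                                  include_hindbrain = FALSE) {
  response <- match.arg(response)
  stopifnot(is.data.frame(concordance),
            all(c("category", "pooled_sdi", "receptor_score") %in%
                  names(concordance)))
  dat <- as_tibble(concordance)
  if ("included" %in% names(dat)) dat <- filter(dat, .data$included)
  if (!include_hindbrain) dat <- filter(dat, .data$category != "hindbrain")
  dat$category <- factor(dat$category)
  sizes <- count(dat, .data$category)
  if (nrow(sizes) < 2) abort("Need >= 2 categories to fit an interaction.")
  if (any(sizes$n < 2)) {
    abort(paste0("Category with a single region makes the slope ",
                 "unidentifiable: ",
                 paste(sizes$category[sizes$n < 2], collapse = ", ")))
  }
  if (response == "sdi") {
    fit <- lm(pooled_sdi ~ receptor_score * category, data = dat)
    covariate <- "receptor_score"
  } else {
    fit <- lm(receptor_score ~ pooled_sdi * category, data = dat)
    covariate <- "pooled_sdi"
  }
  aov_tab <- anova(fit)
  irow <- grep(":", rownames(aov_tab))
  interaction <- tibble(
    term = rownames(aov_tab)[irow],
    df1 = aov_tab$Df[irow],
    df2 = aov_tab$Df[nrow(aov_tab)],
    statistic = aov_tab$`F value`[irow],
    p_value = aov_tab$`Pr(>F)`[irow]
  )
  structure(
    list(fit = fit, orientation = response, covariate = covariate,
         reference = levels(dat$category)[1], interaction = interaction,
         data = dat),
    class = "concordance_fit"
  )
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat(sprintf(
    "Fiber-receptor interaction model (%s ~ %s x category; reference: %s)\n",
    if (x$orientation == "sdi") "pooled SDI" else "receptor score",
    x$covariate, x$reference))
  cat(sprintf("  interaction: F(%d, %d) = %.3g, p = %.3g\n",
              x$interaction$df1, x$interaction$df2,
              x$interaction$statistic, x$interaction$p_value))
  cat(sprintf("  categories: %s\n",
              paste(levels(x$data$category), collapse = ", ")))
  invisible(x)
}

#' Estimated linear trends per category
#'
#' Extracts the per-category slope of the covariate from the interaction
#' model as a linear contrast of the coefficient vector (reference slope plus
#' the category's interaction coefficient), with delta-method standard errors
#' from the coefficient covariance and a two-sided t-test against zero on the
#' residual degrees of freedom.  This reproduces the "estimated linear
#' trends" of an emmeans/emtrends analysis.
#'
#' @param object A `concordance_fit`.
#' @param conf_level Confidence level of the trend interval.
#' @return A tibble per category: `trend` (response units per covariate
#'   unit), `se`, `df`, `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @examples
#' cats <- tibble::tibble(category = c("thalamus", "hypothalamus"),
#'                        intercept = c(0.1, 0.5), slope = c(0.13, -0.04))
#' sim <- simulate_concordance(cats, regions_per_category = 8, seed = 3)
#' estimate_trends(fit_interaction_model(sim))
#' @export
estimate_trends <- function(object, conf_level = 0.95) {
  stopifnot(inherits(object, "concordance_fit"))
  fit <- object$fit
  beta <- coef(fit)
  V <- vcov(fit)
  cats <- levels(object$data$category)
  df_res <- fit$df.residual
  slope_term <- object$covariate
  purrr::map_dfr(cats, function(cat_i) {
    L <- setNames(numeric(length(beta)), names(beta))
    L[slope_term] <- 1
    inter <- paste0(slope_term, ":category", cat_i)
    if (inter %in% names(beta)) L[inter] <- 1
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tstat <- est / se
    half <- stats::qt(1 - (1 - conf_level) / 2, df_res) * se
    tibble(category = cat_i, trend = est, se = se, df = df_res,
           statistic = tstat, p_value = 2 * pt(-abs(tstat), df_res),
           conf_low = est - half, conf_high = est + half)
  })
}
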