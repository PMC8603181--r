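# Plotting helpers: group box plots per biomarker and an effect overview.

#' Box plot of a biomarker by group
#'
#' @param table Analysis table from [cohort_table()] or
#'   [generate_from_glmm()].
#' @param biomarker Biomarker column to plot.
#' @return A ggplot object.
#' @export
plot_biomarker_groups <- function(table, biomarker) {
  stopifnot(biomarker %in% names(table), "group" %in% names(table))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$group,
                                      y = .data[[biomarker]],
                                      fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = biomarker) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' MCI effect overview across biomarkers
#'
#' MCI coefficients with approximate 95% Wald intervals
#' (`estimate +/- 1.96 SE`) for every fitted biomarker, faceted by category.
#'
#' @param results A results tibble from [results_table()].
#' @param alpha Rows with `p_value < alpha` are highlighted.
#' @return A ggplot object.
#' @export
plot_mci_effects <- function(results, alpha = 0.05) {
  d <- dplyr::filter(results, !is.na(.data$beta_mci))
  d$biomarker <- factor(d$biomarker, levels = rev(results$biomarker))
  d$significant <- !is.na(d$p_value) & d$p_value < alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_mci, y = .data$biomarker,
                                  color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_mci - 1.96 * .data$beta_mci_se,
      xmax = .data$beta_mci + 1.96 * .data$beta_mci_se), height = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free", space = "free_y") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#c0392b",
                                           `FALSE` = "grey50")) +
    ggplot2::labs(x = "MCI effect (model scale)", y = NULL,
                  color = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}
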