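# Diagnostic plots and their underlying data tables. Every plot has a
# plain-table twin so reports can be generated without graphics.

#' Scatter-plot data for a harmonised set
#'
#' Per-SNP exposure and outcome betas with standard errors, oriented so the
#' exposure beta is non-negative (the orientation under which fitted lines
#' are drawn).
#'
#' @param h An `mr_harmonised` set.
#' @return A tibble `rsid`, `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @export
mr_scatter_data <- function(h) {
  flip <- h$beta_exp < 0
  tibble(rsid = h$rsid,
         beta_exp = ifelse(flip, -h$beta_exp, h$beta_exp),
         se_exp = h$se_exp,
         beta_out = ifelse(flip, -h$beta_out, h$beta_out),
         se_out = h$se_out)
}

#' Funnel-plot data for a harmonised set
#'
#' Per-SNP Wald ratios against their precision (1/se).
#'
#' @param h An `mr_harmonised` set.
#' @return A tibble `rsid`, `ratio`, `precision`.
#' @export
mr_funnel_data <- function(h) {
  wr <- wald_ratios(h)
  tibble(rsid = wr$rsid, ratio = wr$ratio, precision = 1 / wr$se)
}

#' SNP-level scatter plot with fitted causal slopes
#'
#' @param h An `mr_harmonised` set.
#' @param fits Optional list of `mr_estimate` objects whose slopes (and the
#'   Egger intercept, when present) are drawn.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h, fits = NULL) {
  d <- mr_scatter_data(h)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = paste("SNP effect on", attr(h, "exposure_label")),
                  y = paste("SNP effect on", attr(h, "outcome_label")))
  if (!is.null(fits)) {
    lines <- dplyr::bind_rows(lapply(fits, function(f)
      tibble(method = f$method, intercept = f$intercept %||% 0,
             slope = f$beta)))
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$method)) +
      ggplot2::labs(colour = "method")
  }
  p
}

#' Funnel plot of per-SNP ratios against precision
#'
#' @param h An `mr_harmonised` set.
#' @param beta Optional pooled estimate to draw as a vertical reference.
#' @return A ggplot object.
#' @export
plot_mr_funnel <- function(h, beta = NULL) {
  d <- mr_funnel_data(h)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "per-SNP causal estimate", y = "precision (1/se)")
  if (!is.null(beta))
    p <- p + ggplot2::geom_vline(xintercept = beta, linetype = 2)
  p
}

#' @export
autoplot.mr_harmonised <- function(object, ...) plot_mr_scatter(object, ...)

#' Forest-style attenuation plot for a multivariable MR report
#'
#' Draws univariable and covariable-adjusted odds ratios side by side per
#' (exposure, outcome) cell, the usual presentation of confounder-adjustment
#' results.
#'
#' @param results A tibble from [run_mvmr()].
#' @return A ggplot object.
#' @export
plot_mvmr_attenuation <- function(results) {
  d <- results |>
    dplyr::filter(!is.na(.data$beta_adjusted)) |>
    tidyr::pivot_longer(c("beta_univariable", "beta_adjusted"),
                        names_to = "model", values_to = "beta") |>
    dplyr::mutate(
      se = ifelse(.data$model == "beta_univariable",
                  .data$se_univariable, .data$se_adjusted),
      model = ifelse(.data$model == "beta_univariable", "univariable",
                     paste("adjusted for", .data$adjusted_for)),
      cell = paste(.data$exposure, "→", .data$outcome))
  ggplot2::ggplot(d, ggplot2::aes(x = exp(.data$beta), y = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = exp(.data$beta - 1.96 * .data$se),
      xmax = exp(.data$beta + 1.96 * .data$se)), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~cell, scales = "free_y") +
    ggplot2::labs(x = "OR per 1-SD exposure", y = NULL)
}
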