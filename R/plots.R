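# ggplot2 displays for scan results and variance components.

#' Forest plot of a signature scan
#'
#' Point estimates with 95% confidence intervals per analyte, grouped by
#' analyte class; analytes with p <= 0.05 are emphasised. Linear-route
#' estimates are differences in log10 concentration, logistic-route
#' estimates log odds-ratios, so the two routes are faceted apart.
#'
#' @param scan A `cvl_signature_scan` from [signature_scan()].
#' @return A ggplot object.
#' @export
plot_signature_forest <- function(scan) {
  lev <- rev(unique(scan$analyte))
  d <- scan %>%
    filter(!.data$skipped) %>%
    mutate(analyte = factor(.data$analyte, levels = lev))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate,
    y = .data$analyte,
    colour = .data$significant
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::facet_grid(class ~ route, scales = "free", space = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(
      x = "estimate (log10 difference | log odds-ratio) with 95% CI",
      y = NULL,
      title = paste0("Signature: ", unique(scan$exposure),
                     if (isTRUE(scan$adjusted[1])) " (adjusted)" else "")
    ) +
    ggplot2::theme_bw() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}

#' @export
autoplot.cvl_signature_scan <- function(object, ...) {
  plot_signature_forest(object)
}

#' Dot plot of per-analyte intraclass correlations
#'
#' @param vc_table Output of [icc_scan()].
#' @return A ggplot object.
#' @export
plot_icc <- function(vc_table) {
  d <- vc_table %>%
    mutate(analyte = factor(.data$analyte, levels = rev(vc_table$analyte)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$icc, y = .data$analyte)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$icc_ci_lo,
                                         xmax = .data$icc_ci_hi),
                            height = 0, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::facet_grid(class ~ ., scales = "free_y", space = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "ICC (between-woman share of log10 variance)",
                  y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
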