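#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Forest plot of abundance-model coefficients
#'
#' @param object A `bb_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bb_fit <- function(object, ...) {
  d <- object$coefficients
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "estimate (log-odds)", y = NULL,
                  title = "Beta-binomial abundance model") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential-expression results
#'
#' @param de DE tibble from [fit_age_sex_de()] (one stratum).
#' @param q_thresh Highlight threshold (default 0.05).
#' @return A ggplot.
#' @export
plot_volcano <- function(de, q_thresh = 0.05) {
  d <- dplyr::mutate(de, sig = .data$q_value < q_thresh)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = -log10(.data$p_value),
                                  colour = .data$sig)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change per decade",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Predicted-vs-chronological age with the bias curve
#'
#' @param object Output of [fit_bias_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clock_bias <- function(object, ...) {
  d <- object$predictions
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chronological_age,
                                  y = .data$predicted_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$bias_fitted),
                       colour = "red") +
    ggplot2::labs(x = "chronological age (years)",
                  y = "expression-predicted age (years)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise sharing or correlation table
#'
#' @param pairs Tibble with cell_type_a, cell_type_b and a value column.
#' @param value Column to fill by (default `"rho2"`).
#' @return A ggplot.
#' @export
plot_sharing_heatmap <- function(pairs, value = "rho2") {
  sym <- dplyr::bind_rows(
    pairs,
    dplyr::rename(pairs, cell_type_a = "cell_type_b",
                  cell_type_b = "cell_type_a"))
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$cell_type_a,
                                    y = .data$cell_type_b,
                                    fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
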