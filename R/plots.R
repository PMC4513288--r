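#' Plot methods
#'
#' `autoplot()` methods giving the field's standard displays: log-scale
#' relative-abundance bars, knockdown ratios with dispersion on a log axis,
#' ERG attenuation time courses with significance stars, and dilution
#' standard curves.
#'
#' @param object The fitted/summarized object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name retinawalk-autoplot
NULL

#' @rdname retinawalk-autoplot
#' @export
autoplot.abundance_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$gene, -.data$rel_to_reference),
                                       y = .data$rel_to_reference)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = paste0("abundance relative to ", attr(object, "reference")),
                  title = "Length-normalized read-count abundance") +
    ggplot2::theme_minimal()
}

#' @rdname retinawalk-autoplot
#' @export
autoplot.knockdown_table <- function(object, ...) {
  d <- dplyr::filter(object, !.data$is_reference)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$ratio_vs_control,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ratio_vs_control - .data$sd,
                                        ymax = .data$ratio_vs_control + .data$sd),
                           position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mRNA relative to untreated control",
                  title = "RNAi knockdown (efficiency-corrected comparative Cq)") +
    ggplot2::theme_minimal()
}

#' @rdname retinawalk-autoplot
#' @export
autoplot.erg_timecourse <- function(object, ...) {
  ctrl <- attr(object, "control")
  d <- dplyr::filter(object, .data$position != "pooled")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$mean_mv,
                                  colour = .data$position)) +
    ggplot2::geom_hline(data = ctrl,
                        ggplot2::aes(yintercept = .data$mean_mv,
                                     colour = as.character(.data$position)),
                        linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_mv - .data$se_mv,
                                          ymax = .data$mean_mv + .data$se_mv)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -1.2,
                       show.legend = FALSE) +
    ggplot2::labs(x = "days after injection", y = "ERG amplitude (mV, mean ± se)",
                  colour = "position",
                  title = "ERG attenuation time course (dotted: control level)") +
    ggplot2::theme_minimal()
}

#' @rdname retinawalk-autoplot
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$log10_dilution, y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10 dilution", y = "Cq",
                  title = sprintf("Standard curve: slope %.3f, E = %.1f%%",
                                  object$slope, 100 * object$efficiency)) +
    ggplot2::theme_minimal()
}
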