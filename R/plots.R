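#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a response matrix as a signed tile map
#'
#' @param object A [response_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.response_matrix <- function(object, ...) {
  long <- tidy(object)
  long$parameter <- factor(long$parameter, levels = unique(long$parameter))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$flux,
                                     fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$coefficient, 2))) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "perturbed total", y = "responding flux",
                  fill = "response") +
    ggplot2::theme_minimal()
}

#' Plot a mass-action target scan
#'
#' Closed-form coefficients (points) over finite-perturbation coefficients
#' (lines), per competitor flux, against the total target level.
#'
#' @param object A `target_scan` from [scan_target()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.target_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$total_target,
                                       colour = .data$flux)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$R_T_numeric)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$R_T_analytic), size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total target", y = "flux response to total target",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a polysome-model scan
#'
#' Formula coefficients (points) over simulator finite-perturbation
#' coefficients (lines), faceted by the perturbed parameter.
#'
#' @param object A `polysome_scan` from [polysome_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.polysome_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$total_ribosome,
                                       colour = .data$flux)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$numeric)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$formula), size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter)) +
    ggplot2::labs(x = "total ribosome pool", y = "flux response",
                  colour = "flux of") +
    ggplot2::theme_minimal()
}

#' Histogram of a genome response distribution
#'
#' @param object A `genome_response`.
#' @param binwidth Histogram bin width.
#' @param ... Unused.
#' @return A ggplot with a reference line at a response of 1.
#' @exportS3Method ggplot2::autoplot
autoplot.genome_response <- function(object, binwidth = 0.1, ...) {
  ggplot2::ggplot(object$per_gene, ggplot2::aes(x = .data$coefficient)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#4477aa",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "flux response to total ribosome pool",
                  y = "genes") +
    ggplot2::theme_minimal()
}
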