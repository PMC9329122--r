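# ggplot2 displays for the main result types

#' Plot a DR track along the genome
#'
#' @param object A `dr_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dr_track <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$dr)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "Depletion Rank",
                  title = "Depletion Rank along the genome") +
    ggplot2::theme_minimal()
}

#' Plot per-class saturation with confidence intervals
#'
#' @param object A `saturation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_report <- function(object, ...) {
  d <- as_tibble(object)
  xcol <- if ("class" %in% names(d)) "class" else "label"
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[xcol]], y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.25) +
    {if ("scope" %in% names(d)) ggplot2::facet_wrap(~scope)} +
    ggplot2::labs(x = NULL, y = "saturation",
                  title = "Mutation-class saturation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the fraction of rare variants by DR bin
#'
#' @param frv Output of [frv_by_dr()].
#' @return A ggplot.
#' @export
plot_frv_by_dr <- function(frv) {
  ggplot2::ggplot(frv, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                    y = .data$frv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Depletion Rank bin midpoint",
                  y = "fraction of rare variants",
                  title = "Rare-variant fraction by Depletion Rank") +
    ggplot2::theme_minimal()
}
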