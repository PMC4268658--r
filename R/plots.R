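# ggplot2 display helpers for the main result types.

#' Volcano-style plot of a DMR call result
#'
#' Methylation-level difference (case minus control) against -log10 adjusted
#' value, coloured by direction.
#'
#' @param object An `epigerm_dmr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epigerm_dmr
#' @export
autoplot.epigerm_dmr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$q, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "methylation difference (case - control)",
                  y = expression(-log[10] ~ q), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Metaplot of a coverage profile
#'
#' Mean reads-per-million per offset bin across regions, the standard
#' region-anchored metaplot.
#'
#' @param object An `epigerm_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epigerm_profile
#' @export
autoplot.epigerm_profile <- function(object, ...) {
  df <- tibble(offset = object$offsets + object$binsize / 2,
               mean_rpm = colMeans(object$matrix))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_rpm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("distance from %s (bp)", object$anchor),
                  y = "mean RPM") +
    ggplot2::theme_minimal()
}

#' Bar plot of repeat-family expression fold changes
#'
#' @param ratios Tibble from [expression_ratio()].
#' @return A ggplot object; the dashed line marks fold change 1.
#' @export
plot_expression_ratio <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$repeat_family,
                                       y = .data$fold_change)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fold change (case / control)") +
    ggplot2::theme_minimal()
}

#' Methylation profile along repeat consensus sequences
#'
#' Per-CG methylation level by consensus position, one panel per element;
#' positions flagged `plot_excluded` (the low-coverage element start) are
#' dropped, following the convention for consensus metaplots.
#'
#' @param profile Tibble from [consensus_meth_profile()].
#' @return A ggplot object.
#' @export
plot_consensus_profile <- function(profile) {
  df <- profile[!profile$plot_excluded, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$level)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~element_name, scales = "free_x") +
    ggplot2::labs(x = "consensus position (bp)", y = "CG methylation level") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
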