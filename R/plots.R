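# ggplot2 views of the main result types.

#' Histogram of window methylation levels
#' @param object a `window_methylome`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.window_methylome <- function(object, ...) {
  ggplot2::ggplot(object[object$valid, ], ggplot2::aes(x = .data$level)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey35") +
    ggplot2::labs(x = "window methylation level", y = "windows") +
    ggplot2::theme_minimal()
}

#' Cumulative methylation distributions for element vs other windows
#'
#' The visual companion of [ks_methylation_association()]: empirical CDFs of
#' window methylation levels for element-bearing and remaining valid windows.
#'
#' @param m a `window_methylome`.
#' @param element_windows window labels (see [ks_methylation_association()]).
#' @return a ggplot.
#' @export
plot_methylation_cdf <- function(m, element_windows) {
  flag <- as_window_flag(m, element_windows)
  df <- tibble(level = m$level[m$valid],
               group = if_else(flag[m$valid], "element windows", "other windows"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, colour = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "window methylation level", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Distance-decay profile of the methylation association
#' @param decay tibble from [distance_decay()].
#' @return a ggplot of D against distance, points sized by -log10 p.
#' @export
plot_distance_decay <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes(x = .data$distance / 1e3, y = .data$d_max)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = -log10(.data$p_value))) +
    ggplot2::labs(x = "distance from element (kb)", y = expression(D[max]),
                  size = expression(-log[10] * p)) +
    ggplot2::theme_minimal()
}

#' Heterozygosity by desert stratum
#' @param x a `nahr_assoc` from [het_by_stratum()].
#' @return a ggplot bar chart of mean heterozygosity per stratum.
#' @export
plot_het_strata <- function(x) {
  s <- x$extra$strata
  ggplot2::ggplot(s, ggplot2::aes(x = .data$stratum, y = .data$mean_het)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_het - .data$sd_het,
                                        ymax = .data$mean_het + .data$sd_het),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "mean structural heterozygosity (2pq)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
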