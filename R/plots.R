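# ggplot2 views of the result objects.

#' @export
autoplot.metagene_profile <- function(object, ...) {
  d <- tidy(object)
  nb <- object$params$n_bins
  d$pos <- d$bin + nb * (as.integer(d$region) - 1L)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = c(nb, 2 * nb) + 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, nb + 0.5, 2 * nb + 0.5, 3 * nb),
      labels = c(sprintf("-%d kb", object$params$flank %/% 1000), "TSS", "TES",
                 sprintf("+%d kb", object$params$flank %/% 1000))
    ) +
    ggplot2::labs(x = NULL, y = "tag density (reads / (total reads x bp))") +
    ggplot2::theme_minimal()
}

#' Plot a metagene profile
#'
#' @param x A `metagene_profile`.
#' @param ... Passed to [autoplot()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(x, ...) autoplot(x, ...)

#' @export
autoplot.distribution_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$region_class, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of islands") +
    ggplot2::theme_minimal()
}

#' Scatter plot of cross-lineage enrichment ratios
#'
#' One point per enrichment unit (promoter or peak), the view in which the
#' cross-lineage correlation is computed.
#'
#' @param records Enrichment tibble with `ratio_a` / `ratio_b` columns.
#' @param labels Axis labels for the two lineages.
#' @return A ggplot object, annotated with the Pearson correlation.
#' @export
plot_enrichment_scatter <- function(records, labels = c("A", "B")) {
  r <- enrichment_correlation(records)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$ratio_a, y = .data$ratio_b)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                      label = sprintf("r = %.2f (n = %d)", r$estimate, r$n)) +
    ggplot2::labs(x = sprintf("%s enrichment (tags/bp)", labels[1]),
                  y = sprintf("%s enrichment (tags/bp)", labels[2])) +
    ggplot2::theme_minimal()
}
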