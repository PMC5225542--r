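#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a filter ledger
#'
#' Bar chart of loci removed per cascade step.
#'
#' @param object A `filter_ledger` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.filter_ledger <- function(object, ...) {
  df <- dplyr::mutate(object, step = factor(.data$step, levels = .data$step))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loci_removed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$loci_out), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "loci removed",
                  title = "SNP filter cascade",
                  subtitle = "labels: loci retained after each step") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Quantile-quantile plot of outlier-scan p-values
#'
#' @param object A [qq_data()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qq_data <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(-log[10] ~ "expected p"),
                  y = expression(-log[10] ~ "observed p")) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise differentiation matrix
#'
#' @param object A `pairwise_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pairwise_matrix <- function(object, ...) {
  df <- tidy.pairwise_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pop_a, y = .data$pop_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$statistic) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Map of a dispersal snapshot
#'
#' @param object A particle tibble (e.g. one snapshot of
#'   [run_dispersal()]).
#' @param ... Unused.
#' @return A ggplot of particle positions coloured by seed region.
#' @export
plot_dispersal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       colour = .data$seed_region)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude", colour = "seed") +
    ggplot2::theme_minimal()
}
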