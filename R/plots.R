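#' Plot CTA scores for annotated clusters
#'
#' One panel per cluster showing the top-scoring cell types as horizontal
#' bars, significant winners highlighted.
#'
#' @param object A `cta_annotation` object.
#' @param n_top Cell types shown per cluster.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.cta_annotation <- function(object, n_top = 5, ...) {
  df <- object$scores |>
    filter(.data$rank <= n_top) |>
    mutate(
      cluster = paste0("cluster ", .data$cluster_id),
      winner = .data$rank == 1L & .data$fdr <= object$params$fdr_cutoff
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cta,
                                   y = stats::reorder(.data$cell_type, .data$cta),
                                   fill = .data$winner)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70")) +
    ggplot2::labs(x = "CTA score", y = NULL,
                  title = "Cell-type activity by cluster") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Plot marker weights against gene frequency
#'
#' Visualizes the down-weighting curve: each point is a gene, placed by its
#' frequency across cell types and the weight it receives.
#'
#' @param freq Frequency tibble from [gene_frequency()].
#' @return A ggplot object.
#' @export
plot_marker_weights <- function(freq) {
  w <- marker_weight(freq)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$f, y = .data$weight)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = distinct(w, .data$f, .data$weight),
                       colour = "#2166ac") +
    ggplot2::scale_y_continuous(limits = c(1, 2)) +
    ggplot2::labs(x = "frequency across cell types f(g)", y = "weight w(g)",
                  title = "Marker down-weighting") +
    ggplot2::theme_minimal()
}

#' Bar plot of search results by cell type
#'
#' The summary view of a gene search: number of matching cell clusters per
#' inferred cell type.
#'
#' @param rows Search result tibble from [search_clusters()].
#' @return A ggplot object.
#' @export
plot_search_summary <- function(rows) {
  df <- summarize_by_cell_type(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_clusters,
                                   y = stats::reorder(.data$cell_type, .data$n_clusters))) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "matching cell clusters", y = NULL,
                  title = "Search results by cell type") +
    ggplot2::theme_minimal()
}
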