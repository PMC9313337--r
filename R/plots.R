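#' Plot pathway importances
#'
#' Horizontal bar chart of mean-decrease-Gini importance, most important
#' pathway on top.
#'
#' @param object An `enrichment_result`.
#' @param top_n Show at most this many pathways.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top_n = 20, ...) {
  df <- head(object$importance, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mdg,
    y = stats::reorder(.data$pathway, .data$mdg))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean decrease Gini", y = NULL,
                  title = "Pathway importance") +
    ggplot2::theme_minimal()
}

#' Bump chart of pathway ranks across strategies
#'
#' @param comparison Output of [compare_rankings()].
#' @param top_n Keep pathways reaching at least this rank in some strategy.
#' @return A ggplot object.
#' @export
plot_rank_comparison <- function(comparison, top_n = 10) {
  df <- comparison$ranks
  keep <- unique(df$pathway[df$rank <= top_n])
  df <- df[df$pathway %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strategy, y = .data$rank,
                                   group = .data$pathway,
                                   colour = .data$pathway)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse(breaks = seq_len(max(df$rank))) +
    ggplot2::labs(x = NULL, y = "Importance rank",
                  title = "Pathway ranking by reconstruction strategy") +
    ggplot2::theme_minimal()
}

#' Plot reconstruction edge accounting
#'
#' Stacked per-strategy counts of kept, removed (self-loop and cyclic) and
#' added edges.
#'
#' @param object A `reconstruction_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reconstruction_report <- function(object, ...) {
  df <- object$per_strategy |>
    tidyr::pivot_longer(c("n_kept", "n_self_loop", "n_cycle_removed", "n_added"),
                        names_to = "class", values_to = "count") |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c("n_kept", "n_cycle_removed",
                                            "n_self_loop", "n_added"),
                                 labels = c("kept", "cycle removed",
                                            "self-loop", "added")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strategy, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Edges", fill = NULL,
                  title = "Edge accounting by strategy") +
    ggplot2::theme_minimal()
}
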