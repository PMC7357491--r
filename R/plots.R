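#' Plot a score matrix (per-strain attribute scores)
#'
#' One panel per strain, attribute scores as bars colored by criterion —
#' the per-strain attribute-score profile of the multicriteria analysis.
#'
#' @param object A [score_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$attribute, y = .data$score,
                                   fill = .data$criterion)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~strain, ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "attribute score (0-1)", fill = "criterion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' Plot a ranking result (weighted totals per scenario)
#'
#' Stacked per-criterion weighted subtotals per strain, one panel per
#' scenario; bar height is the total weighted score used for ranking.
#'
#' @param object A `ranking_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranking_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, y = .data$subtotal,
                                   fill = .data$criterion)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = NULL, y = "weighted score", fill = "criterion") +
    ggplot2::theme_minimal()
}

#' Plot a velocity matrix (metabolic fingerprint heat map)
#'
#' Strain x substrate heat map of gated degradation velocities (OD/h);
#' zero cells are substrates without significant positive degradation.
#'
#' @param object A [degradation_velocities()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$substrate, y = .data$strain,
                                   fill = .data$velocity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "velocity (OD/h)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}
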