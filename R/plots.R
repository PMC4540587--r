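#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' per-branch ILS levels ([branch_summary()]), the hemiplasy probability
#' curve ([hemiplasy_table()]), placement support profiles
#' ([support_counts()]) and motif composition ([motif_matrix()]).
#'
#' @param object a result object.
#' @param ... unused.
#' @return a `ggplot`.
#' @name retroils-plots
NULL

#' @rdname retroils-plots
#' @method autoplot branch_ils
#' @export
autoplot.branch_ils <- function(object, ...) {
  df <- dplyr::filter(object, .data$total_markers > 0) |>
    tidyr::pivot_longer(cols = c("conflict_free", "ils_2", "ils_3", "ils_4plus"),
                        names_to = "class", values_to = "n") |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c("conflict_free", "ils_2", "ils_3", "ils_4plus"),
                                 labels = c("conflict-free", "ILS across 2",
                                            "ILS across 3", "ILS across >=4")))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$branch), y = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("#3B6FB6", "#57A773", "#E8A33D", "#C33C54")) +
    ggplot2::labs(x = "branch (child-node id)", y = "insertion events",
                  fill = NULL, title = "Per-branch ILS of RE insertions") +
    ggplot2::theme_minimal()
}

#' @rdname retroils-plots
#' @method autoplot hemiplasy_tbl
#' @export
autoplot.hemiplasy_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_events, y = .data$p_hemiplasy)) +
    ggplot2::geom_line(colour = "#C33C54") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "ILS duration (speciation events)",
                  y = "probability of hemiplasy",
                  title = "Hemiplasy under stochastic allele sorting") +
    ggplot2::theme_minimal()
}

#' @rdname retroils-plots
#' @method autoplot support_profile
#' @export
autoplot.support_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$candidate, -.data$n_support),
                               y = .data$n_support)) +
    ggplot2::geom_col(fill = "#3B6FB6") +
    ggplot2::labs(x = NULL, y = "diagnostic conflict-free markers",
                  title = "RE support for alternative placements") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname retroils-plots
#' @method autoplot motif_matrix
#' @export
autoplot.motif_matrix <- function(object, ...) {
  df <- tidy.motif_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$frequency,
                                   fill = .data$nucleotide)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(A = "#57A773", C = "#3B6FB6",
                                          G = "#E8A33D", T = "#C33C54")) +
    ggplot2::labs(x = "motif position (5' to 3')", y = "frequency",
                  title = "Target-site-duplication motif composition") +
    ggplot2::theme_minimal()
}
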