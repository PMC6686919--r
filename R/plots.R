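# ggplot2 views of the screening results.

#' Plot enzyme/pathway prevalence
#'
#' Bar chart of [summarize_counts()] percentages.
#'
#' @param summary Output of [summarize_counts()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$percentage),
                               y = .data$percentage,
                               fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Proteomes with feature (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Presence/absence heat map of a pathway matrix
#'
#' Proteomes x pathways tile plot, faceted by clade when a `phylum` column
#' is present.
#'
#' @param object A `pathway_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_matrix
#' @export
autoplot.pathway_matrix <- function(object, ...) {
  path_cols <- grep("^pathway_", names(object), value = TRUE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("proteome_id", intersect("phylum", names(object)),
                                  path_cols)],
    dplyr::all_of(path_cols), names_to = "pathway", values_to = "present")
  long$pathway <- sub("^pathway_", "", long$pathway)
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$pathway, y = .data$proteome_id,
                                    fill = .data$present)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "#2c7fb8")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if ("phylum" %in% names(long)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$phylum),
                                 scales = "free_y", space = "free_y")
  }
  p
}

#' Proteome-size distributions of a group comparison
#'
#' Jittered per-proteome sizes of the pathway-positive and -negative groups
#' with group means.
#'
#' @param object A `reserve_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reserve_comparison
#' @export
autoplot.reserve_comparison <- function(object, ...) {
  df <- tibble::tibble(
    group = c(rep("with", object$n_with), rep("without", object$n_without)),
    proteome_size = c(object$sizes_with, object$sizes_without))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$proteome_size)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, color = "#2c7fb8") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          color = "#d62728") +
    ggplot2::labs(title = object$pathway_id,
                  subtitle = sprintf("t = %.2f, p = %.2g",
                                     object$t_statistic, object$p_value),
                  x = NULL, y = "Proteome size (proteins)") +
    ggplot2::theme_minimal()
}
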