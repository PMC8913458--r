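#' Plot a myeloma-clone frequency trajectory
#'
#' Clone frequency over time from [track_clone()], on a square-root
#' scale so low-burden timepoints stay visible.
#'
#' @param track Tibble from [track_clone()] (`date`, `freq`).
#' @return A ggplot object.
#' @export
plot_clone_tracking <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$date, y = .data$freq)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_sqrt(labels = function(x) sprintf("%.1f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "MM clone frequency",
                  title = "MM clone frequency over time") +
    ggplot2::theme_minimal()
}

#' Plot a clone-rank frequency spectrum
#'
#' @param rep An [repertoire()].
#' @param n_top Number of top-ranked clonotypes to show.
#' @return A ggplot object.
#' @export
plot_repertoire_spectrum <- function(rep, n_top = 25L) {
  df <- tibble::as_tibble(rep) |>
    dplyr::slice_head(n = n_top) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$freq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = c(0.05, 1 / 3), linetype = "dashed",
                        color = "grey30") +
    ggplot2::labs(x = "clonotype rank", y = "frequency",
                  title = paste0(rep_sample_id(rep), " (", rep_chain(rep),
                                 ") clone spectrum"),
                  subtitle = "dashed: 5% overlap and 33.3% overrepresentation thresholds") +
    ggplot2::theme_minimal()
}

#' Plot a cohort category summary
#'
#' Stacked percentage bars of result categories per group, the usual
#' display for cohort-level NGS or flow results.
#'
#' @param summary Tibble from [summarize_cohort()].
#' @param group Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_cohort_summary <- function(summary, group = "group") {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data[[group]], y = .data$percent,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "% of samples") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.concordance_result <- function(object, ...) {
  df <- tidy(object)
  df$ngs <- ifelse(df$ngs, "NGS +", "NGS -")
  df$mfc <- ifelse(df$mfc, "MFC +", "MFC -")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mfc, y = .data$ngs)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count), color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("Agreement %.1f%%, Cohen's kappa %.3f",
                      object$percent_agreement, object$kappa),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
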