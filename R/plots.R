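# ggplot2 displays for the main result types.

#' Plot the sex-bias distribution, Z versus autosomes
#'
#' Boxplots of per-feature log2 M:F ratios for the Z chromosome and the
#' pooled autosomes, with the equal-expression line at 0. Outlier-flagged
#' records are dropped from the display.
#'
#' @param bias A [sex_bias_table()] (optionally with a `tissue` column for
#'   facetting).
#' @param z_chrom Name of the Z chromosome.
#' @return A ggplot object.
#' @export
plot_sex_bias <- function(bias, z_chrom = "Z") {
  dat <- bias |>
    filter(!.data$outlier) |>
    mutate(group = ifelse(.data$chrom == z_chrom, "Z", "autosomes"))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$log2_mf,
                                         fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, colour = "red", linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "M:F")) +
    ggplot2::theme_minimal()
  if ("tissue" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(~tissue)
  }
  p
}

#' @export
autoplot.sex_bias_tbl <- function(object, ...) plot_sex_bias(object, ...)

#' Plot a sliding-window scan
#'
#' Per-gene log2 M:F points with the moving-average fold-change and
#' amplitude lines along the chromosome.
#'
#' @param scan A [window_scan()] result.
#' @param bias Optional matching [sex_bias_table()] for the per-gene points.
#' @return A ggplot object.
#' @export
plot_window_scan <- function(scan, bias = NULL) {
  mid <- (scan$window_start + scan$window_end) / 2
  dat <- mutate(as_tibble(scan), mid = mid / 1e6)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid))
  if (!is.null(bias)) {
    p <- p + ggplot2::geom_point(
      data = filter(bias, !.data$outlier),
      ggplot2::aes(x = .data$position / 1e6, y = .data$log2_mf),
      colour = "grey60", size = 0.5, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_log2_mf,
                                    colour = "fold-change"), na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_amplitude,
                                    colour = "amplitude"), na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c("fold-change" = "darkgreen", "amplitude" = "blue"),
      name = NULL
    ) +
    ggplot2::labs(x = "position (Mb)", y = expression(log[2] ~ "M:F")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.window_scan_tbl <- function(object, ...) plot_window_scan(object, ...)

#' Bar chart of alternative-splicing mode tallies
#'
#' @param events Output of [classify_splice_events()]; `"complex"` rows are
#'   excluded.
#' @return A ggplot object.
#' @export
plot_splice_modes <- function(events) {
  dat <- events |>
    filter(.data$event_type != "complex") |>
    count(.data$event_type)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$event_type, -.data$n),
                                    y = .data$n, fill = .data$event_type)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "events") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar chart of lncRNA class proportions
#'
#' @param classes Output of [classify_lncrna()].
#' @return A ggplot object.
#' @export
plot_lncrna_classes <- function(classes) {
  dat <- classes |> count(.data$class) |>
    mutate(percent = 100 * .data$n / sum(.data$n))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$percent,
                                    fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of lncRNAs") +
    ggplot2::theme_minimal()
}

#' Stacked bars of poly(A) site-count categories per group
#'
#' @param distribution `distribution` tibble from [polya_sites_per_gene()].
#' @return A ggplot object.
#' @export
plot_polya_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$group, y = .data$n_genes,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "genes", fill = "poly(A) sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
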