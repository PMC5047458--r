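#' Plot the exon/intron structure of gene models
#'
#' Exons are drawn as boxes on a line spanning the gene body, one track per
#' model, in the style of a gene-structure diagram.
#'
#' @param models A `gene_model` or list of them.
#' @return A ggplot object.
#' @export
plot_gene_models <- function(models) {
  if (inherits(models, "gene_model")) models <- list(models)
  feat <- purrr::imap(models, function(m, k) {
    tidy(m) |> mutate(track = factor(k))
  }) |> dplyr::bind_rows()
  ex <- feat |> filter(feature == "exon")
  spans <- feat |>
    summarise(start = min(start), end = max(end), .by = track)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = spans,
                          ggplot2::aes(x = start, xend = end,
                                       y = track, yend = track)) +
    ggplot2::geom_rect(data = ex,
                       ggplot2::aes(xmin = start, xmax = end,
                                    ymin = as.integer(track) - 0.25,
                                    ymax = as.integer(track) + 0.25),
                       fill = "firebrick") +
    ggplot2::labs(x = "contig position (bp)", y = "gene model") +
    ggplot2::theme_minimal()
}

#' Plot the wells recovered by a pooled screen
#'
#' One panel per positive plate, positive wells marked on the 16 x 24 grid.
#'
#' @param result A `screen_result`.
#' @return A ggplot object.
#' @export
plot_screen_result <- function(result) {
  wells <- result$step3_positive_wells
  ggplot2::ggplot(wells, ggplot2::aes(x = col, y = row)) +
    ggplot2::geom_point(colour = "firebrick", size = 3) +
    ggplot2::facet_wrap(~plate, labeller = ggplot2::label_both) +
    ggplot2::scale_y_reverse(breaks = seq(1, 16, 3),
                             labels = LETTERS[seq(1, 16, 3)]) +
    ggplot2::scale_x_continuous(limits = c(1, 24)) +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_bw()
}
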