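#' Enrichment-change scatter for a timepoint
#'
#' Plots the injury response in the OL fraction against the differential
#' enrichment (interaction) term, the two axes the filtration reasons about,
#' with the high-confidence verdict overlaid when supplied.
#'
#' @param profile Tibble from [enrichment_profile()].
#' @param timepoint Post-injury condition to display.
#' @param verdicts Optional verdict tibble from [two_arm_filter()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(profile, timepoint, verdicts = NULL) {
  x <- dplyr::filter(profile, .data$condition == !!timepoint)
  x$status <- "not DEG"
  if (!is.null(verdicts)) {
    v <- verdicts[verdicts$timepoint == timepoint, ]
    x$status[x$gene_id %in% v$gene_id] <- "raw DEG"
    x$status[x$gene_id %in% v$gene_id[v$high_confidence]] <- "high confidence"
  }
  ggplot2::ggplot(
    x,
    ggplot2::aes(.data$ol_log2fc_vs_naive, .data$delta_log2fc, colour = .data$status)
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-1, 0, 1), linetype = c(2, 1, 2)) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(
      "not DEG" = "grey70", "raw DEG" = "steelblue", "high confidence" = "firebrick"
    )) +
    ggplot2::labs(
      x = expression(log[2] * "FC OL fraction vs naive"),
      y = expression(Delta * log[2] * "FC(OL/total)"),
      title = timepoint
    ) +
    ggplot2::theme_bw()
}
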