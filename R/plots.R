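# ggplot2 views of the main result types.

#' Plot cross-tissue consistency scores
#'
#' Features ordered by rank on the x axis, consistency score
#' (tissues up minus tissues down) on the y axis; features significant in
#' the same direction in every tested tissue are highlighted.
#'
#' @param scores Output of [consistency_scores()].
#' @param highlight Optional feature id(s) to label (e.g. the planted or
#'   focal splicing factor).
#' @return A ggplot object.
#' @export
plot_consistency <- function(scores, highlight = NULL) {
  scores$consistent <- scores$consistent_all_down | scores$consistent_all_up
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$consistent),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "rank (most consistently silenced first)",
                  y = "consistency score (tissues up - tissues down)") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hl <- scores[scores$sf_id %in% highlight, , drop = FALSE]
    p <- p + ggplot2::geom_text(data = hl,
                                ggplot2::aes(label = .data$sf_id),
                                vjust = -0.8, size = 3)
  }
  p
}

#' Plot the distribution of significant dPSI values
#'
#' Histogram of dPSI (tumor - normal) for significant calls, split by
#' microexon status when available.
#'
#' @param calls Output of [differential_psi()].
#' @return A ggplot object.
#' @export
plot_dpsi_distribution <- function(calls) {
  sig <- calls[calls$significant, , drop = FALSE]
  p <- ggplot2::ggplot(sig, ggplot2::aes(x = .data$dpsi))
  if (!is.null(sig$is_microexon)) {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data$is_microexon),
      bins = 40, position = "stack") +
      ggplot2::labs(fill = "microexon")
  } else {
    p <- p + ggplot2::geom_histogram(bins = 40)
  }
  p + ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Delta * "PSI (tumor - normal)"),
                  y = "significant exons") +
    ggplot2::theme_minimal()
}

#' Plot MI correlation against dPSI per exon
#'
#' Scatter of each significant exon's Spearman correlation with the
#' mitotic-index signature (x) against its dPSI in tumors (y), the
#' quadrant view of the proliferation coupling.
#'
#' @param rhos Output of [per_exon_mi_correlation()].
#' @param calls Output of [differential_psi()].
#' @return A ggplot object.
#' @export
plot_mi_quadrants <- function(rhos, calls) {
  df <- dplyr::inner_join(
    calls[calls$significant, c("exon_id", "tissue", "dpsi")],
    rhos[!is.na(rhos$rho), c("exon_id", "tissue", "rho")],
    by = c("exon_id", "tissue"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$dpsi,
                                   colour = .data$dpsi < 0)) +
    ggplot2::geom_point(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue")) +
    ggplot2::labs(x = "Spearman rho (PSI vs mitotic index)",
                  y = expression(Delta * "PSI (tumor - normal)")) +
    ggplot2::theme_minimal()
}

#' @describeIn randomization_test Histogram of the background median
#'   correlations with the observed value marked.
#' @param object A `randomization_test`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.randomization_test <- function(object, ...) {
  df <- tibble::tibble(median_rho = object$background_medians)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_rho)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_median_rho,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "background median Spearman rho",
      y = "background genes",
      title = sprintf("%s background, one-tailed p = %.3g",
                      object$background_kind, object$p_one_tailed)) +
    ggplot2::theme_minimal()
}
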