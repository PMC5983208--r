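#' Volcano plot of a differential methylation table
#'
#' Beta difference against -log10 FDR, colored by call; the dashed guides
#' mark the delta-beta and FDR thresholds the calls used.
#'
#' @param object A `dm_table` from [diff_methylation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dm_table
#' @export
autoplot.dm_table <- function(object, ...) {
  thr <- attr(object, "thresholds") %||% c(alpha = 0.05, delta = 0.15)
  df <- dplyr::filter(tidy(object), !is.na(.data$fdr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_beta,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-thr[["delta"]], thr[["delta"]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(thr[["alpha"]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b",
                                            hypo = "#2980b9",
                                            none = "grey70")) +
    ggplot2::labs(x = expression(Delta * beta ~ "(case - control)"),
                  y = expression(-log[10] ~ "FDR"), colour = "call") +
    ggplot2::theme_minimal()
}

#' Plot DMR span and probe-count summary
#'
#' @param dmrs DMR tibble from [merge_windows()].
#' @return A ggplot object (span in bp vs member probes, by direction).
#' @export
plot_dmr_summary <- function(dmrs) {
  df <- dplyr::mutate(dmrs, span = .data$end - .data$start + 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$span, y = .data$n_probes,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(hyper = "#c0392b",
                                            hypo = "#2980b9")) +
    ggplot2::labs(x = "DMR span (bp)", y = "member probes",
                  colour = "direction") +
    ggplot2::theme_minimal()
}

#' Plot a focal-vs-background category distribution
#'
#' Side-by-side bars of the percentages returned by
#' [category_distribution()].
#'
#' @param dist Tibble from [category_distribution()].
#' @return A ggplot object.
#' @export
plot_category_distribution <- function(dist) {
  long <- tidyr::pivot_longer(dist, c("focal_pct", "background_pct"),
                              names_to = "set", values_to = "pct")
  long$set <- ifelse(long$set == "focal_pct", "focal", "background")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$pct,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of probes", fill = NULL) +
    ggplot2::theme_minimal()
}
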