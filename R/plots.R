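# ggplot2 displays for the main result types.

#' Manhattan-style plot of a DMR scan
#'
#' -log10 p against genomic position, one panel per chromosome, with
#' horizontal guides at the p-value corresponding to each FDR tier's least
#' significant discovery.
#'
#' @param records A `twindmr_scan` tibble from [dmr_scan()] or
#'   [gidmr_scan()].
#' @param q_threshold Tier used to highlight discoveries.
#' @return A ggplot object.
#' @export
plot_dmr_scan <- function(records, q_threshold = 0.25) {
  df <- mutate(records,
               neglog10p = -log10(.data$p),
               discovery = .data$q <= q_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                   y = .data$neglog10p,
                                   colour = .data$discovery)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
      name = sprintf("q <= %.2g", q_threshold)) +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' @method autoplot twindmr_scan
#' @export
autoplot.twindmr_scan <- function(object, ...) plot_dmr_scan(object, ...)

#' Volcano plot of effect size against significance
#'
#' @inheritParams plot_dmr_scan
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, q_threshold = 0.25) {
  df <- mutate(records, neglog10p = -log10(.data$p),
               discovery = .data$q <= q_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$neglog10p,
                                   colour = .data$direction,
                                   alpha = .data$discovery)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                guide = "none") +
    ggplot2::scale_colour_manual(
      values = c(hyper = "firebrick", hypo = "steelblue"),
      na.value = "grey55", name = "direction in cases") +
    ggplot2::labs(x = "disease effect (normalized units)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' Fold enrichment per test with the empirical / exact p-value printed
#' beside each point.
#'
#' @param report A `twindmr_enrichment` tibble (rows from the enrichment
#'   tests, e.g. bound together by [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(report) {
  df <- as_tibble(report)
  if (!"test" %in% names(df)) df$test <- df$method
  df <- mutate(df, label = ifelse(is.na(.data$p), "untestable",
                                  sprintf("p = %.3g", .data$p)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$test)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 3, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "fold enrichment (observed / expected)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot twindmr_enrichment
#' @export
autoplot.twindmr_enrichment <- function(object, ...) plot_enrichment(object)
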