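#' Fold-change vs expressing-fraction plot with the prediction band
#'
#' The standard visualization of the DE caller: each gene's log2 fold
#' change plotted against the fraction of expressing reference cells, the
#' fitted regression line, the prediction band (dashed), the
#' expressing-fraction gate (vertical line) and the called genes
#' highlighted and labelled.
#'
#' @param object a `de_results` tibble from [call_de()]
#' @param label_top number of called genes to label
#' @param ... unused
#' @return a ggplot
#' @method autoplot de_results
#' @export
autoplot.de_results <- function(object, label_top = 10, ...) {
  band <- attr(object, "band")
  min_frac <- attr(object, "min_frac") %||% 0.30
  grid <- tibble(x = seq(min(object$frac_expr_ref), max(object$frac_expr_ref),
                         length.out = 200))
  bd <- predict_band(band, grid$x)
  top <- dplyr::slice_head(dplyr::filter(object, .data$is_de), n = label_top)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frac_expr_ref, y = .data$log2fc)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$is_de), size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(data = bd, ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::geom_line(data = bd, ggplot2::aes(x = .data$x, y = .data$upper),
                       linetype = "dashed", color = "red", inherit.aes = FALSE) +
    ggplot2::geom_line(data = bd, ggplot2::aes(x = .data$x, y = .data$lower),
                       linetype = "dashed", color = "red", inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = min_frac, color = "darkgreen") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "red")) +
    ggplot2::labs(x = "fraction of expressing reference cells",
                  y = "log2 fold change", color = "DE") +
    ggplot2::theme_classic()
}

#' NES distribution of per-cell GSEA results
#'
#' Violin of the normalized enrichment scores of significant cells,
#' optionally split by a grouping vector (e.g. genotype).
#'
#' @param object a `cell_gsea` tibble from [percell_gsea()]
#' @param group optional per-cell grouping vector aligned to the rows
#' @param ... unused
#' @return a ggplot
#' @method autoplot cell_gsea
#' @export
autoplot.cell_gsea <- function(object, group = NULL, ...) {
  df <- dplyr::filter(object, .data$significant, !is.na(.data$nes))
  df$group <- if (is.null(group)) "all cells" else group[match(df$barcode, object$barcode)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$nes)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, size = 0.4, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4, color = "red") +
    ggplot2::labs(x = NULL, y = "NES (significant cells)") +
    ggplot2::theme_classic()
}

#' Bubble plot of per-cluster module summaries
#'
#' Module z-score as color, fraction of expressing cells as bubble size —
#' one bubble per module and cluster.
#'
#' @param summary a tibble from [cluster_summary()]
#' @return a ggplot
#' @export
plot_cluster_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$cluster, y = .data$module)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$frac_expressing, color = .data$z)) +
    ggplot2::scale_color_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(size = "fraction expressing", color = "z-score") +
    ggplot2::theme_classic()
}

#' Log10 relative cluster frequencies between two groups
#'
#' @param composition a `composition_table` from [cluster_composition()]
#' @param group_num,group_den the pair to plot (defaults to the first pair)
#' @return a ggplot
#' @export
plot_composition <- function(composition, group_num = NULL, group_den = NULL) {
  r <- composition$ratios
  if (is.null(group_num)) group_num <- r$group_num[1]
  if (is.null(group_den)) group_den <- r$group_den[1]
  df <- dplyr::filter(r, .data$group_num == !!group_num,
                      .data$group_den == !!group_den)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$log10_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(y = sprintf("log10( freq %s / freq %s )", group_num, group_den)) +
    ggplot2::theme_classic()
}
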