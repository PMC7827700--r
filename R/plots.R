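#' MA plot of a differential-expression result
#'
#' log2 fold change against log2 baseMean, significant genes highlighted.
#'
#' @param de An `sclnc_de` object.
#' @return A ggplot object.
#' @export
plot_ma <- function(de) {
  tab <- ma_table(de)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2_base_mean,
                                    y = .data$log2FoldChange,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "log2 baseMean", y = "log2 fold change",
                  colour = paste0("padj < ", de$alpha),
                  title = paste0(de$contrast, ": ", de$levels[2], " vs ",
                                 de$levels[1]))
}

#' @rdname plot_ma
#' @param object An `sclnc_de` object.
#' @param ... Unused.
#' @method autoplot sclnc_de
#' @export
autoplot.sclnc_de <- function(object, ...) plot_ma(object)

#' PCA plot of pseudobulk samples
#'
#' @param pca An `sclnc_pca` object.
#' @param colour Name of a metadata column to colour by (default
#'   `"cell_type"` if present, else `"timepoint"`, else none).
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, colour = NULL) {
  co <- pca$coords
  if (is.null(colour)) {
    colour <- intersect(c("cell_type", "timepoint"), names(co))[1]
  }
  ve <- pca$var_explained
  p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    )
  if (!is.na(colour) && !is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p
}

#' @rdname plot_pca
#' @param object An `sclnc_pca` object.
#' @param ... Passed to [plot_pca()].
#' @method autoplot sclnc_pca
#' @export
autoplot.sclnc_pca <- function(object, ...) plot_pca(object, ...)

#' Scatter plot of cis-pair fold changes
#'
#' @param pairs Tibble from [cis_pairs()].
#' @return A ggplot object with the Pearson r in the title.
#' @export
plot_cis_pairs <- function(pairs) {
  r <- cis_correlation(pairs)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$lnc_lfc, y = .data$coding_lfc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red3", linewidth = 0.5) +
    ggplot2::labs(x = "lncRNA log2 fold change",
                  y = "coding gene log2 fold change",
                  title = sprintf("cis pairs: r = %.2f (n = %d)",
                                  r$pearson_r, r$n_pairs))
}

#' Histogram of lncRNA mature lengths
#'
#' @param genes Gene tibble with `mature_length`, or a numeric vector.
#' @return A ggplot object (log10 x scale).
#' @export
plot_length_distribution <- function(genes) {
  len <- if (is.data.frame(genes)) genes$mature_length else genes
  ggplot2::ggplot(tibble::tibble(mature_length = len),
                  ggplot2::aes(x = .data$mature_length)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mature length (bp)", y = "lncRNAs")
}

#' Heatmap of pairwise sample distances
#'
#' @param d Symmetric distance matrix from [sample_distances()].
#' @return A ggplot tile plot.
#' @export
plot_sample_distances <- function(d) {
  df <- tibble::tibble(
    a = rep(rownames(d), times = ncol(d)),
    b = rep(colnames(d), each = nrow(d)),
    distance = as.numeric(d)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Euclidean\ndistance") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
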