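#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_line geom_step geom_col labs theme_minimal scale_color_manual
#'   coord_flip
#' @importFrom rlang .data
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression result
#'
#' Z-scored log2 fold change against -log10 FDR, with the call
#' thresholds drawn as dashed cutoffs.
#'
#' @param object a `de_result`.
#' @param spec the [de_call_spec()] whose thresholds to draw.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, spec = de_call_spec(), ...) {
  d <- tidy(object)
  d <- d[!is.na(d$z) & !is.na(d$fdr), ]
  d$called <- d$protein %in% call_de(object, spec)
  p <- ggplot(d, aes(x = .data$z, y = -log10(.data$fdr),
                     color = .data$called)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_vline(xintercept = c(-spec$z_min, spec$z_min),
               linetype = "dashed", color = "red") +
    scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "red"),
                       guide = "none") +
    labs(x = "Z-scored log2 fold change (AD vs Ctl)",
         y = "-log10 FDR") +
    theme_minimal()
  if (!is.null(spec$fdr_max)) {
    p <- p + geom_hline(yintercept = -log10(spec$fdr_max),
                        linetype = "dashed", color = "red")
  }
  p
}

#' Depth-detectability curve
#'
#' @param object a `depth_curve`.
#' @param ... unused.
#' @return A ggplot of detected members against profiling depth, with
#'   the set's median abundance rank marked.
#' @export
autoplot.depth_curve <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$depth, y = .data$detected)) +
    geom_step() +
    geom_point() +
    geom_vline(xintercept = attr(object, "median_rank", exact = TRUE),
               linetype = "dashed", color = "red") +
    labs(x = "profiling depth (top-N most abundant proteins)",
         y = "query-set members detected") +
    theme_minimal()
}

#' Sample PCA plot
#'
#' @param object a `pca_qc`.
#' @param groups optional named group labels to color by.
#' @param ... unused.
#' @return A ggplot of samples on the first two components.
#' @export
autoplot.pca_qc <- function(object, groups = NULL, ...) {
  d <- tidy(object)
  ve <- attr(object, "var_explained", exact = TRUE)
  if (!is.null(groups)) d$group <- groups[d$sample_id]
  p <- ggplot(d, aes(x = .data$PC1, y = .data$PC2)) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    theme_minimal()
  if (!is.null(groups)) {
    p + geom_point(aes(color = .data$group), size = 2)
  } else {
    p + geom_point(size = 2)
  }
}

#' Top of an integrated ranking
#'
#' @param object an `integrated_ranking`.
#' @param n_top number of top proteins to show.
#' @param ... unused.
#' @return A ggplot bar chart of -log10 empirical p for the top
#'   proteins.
#' @export
autoplot.integrated_ranking <- function(object, n_top = 20, ...) {
  d <- head(tidy(object), n_top)
  d$protein <- factor(d$protein, levels = rev(d$protein))
  ggplot(d, aes(x = .data$protein, y = -log10(.data$p_emp))) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "-log10 empirical p (integrated)") +
    theme_minimal()
}
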