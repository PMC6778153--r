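# ggplot2 views of the three result types.

#' Volcano plot of a differential result
#'
#' Log2 ratio (second condition over first) against -log10 q-value, coloured
#' by abundance category, with the fold-change and FDR cutoffs drawn.
#'
#' @param object An `lfq_differential` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lfq_differential <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio,
                                   y = -log10(.data$q_value),
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-thr$logfc_cut, thr$logfc_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(thr$fdr_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 ratio", y = "-log10 FDR q",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Fold-enrichment plot of an over-representation result
#'
#' Fold enrichment of the top terms (all significant terms, or the `top_n`
#' smallest q-values when none is significant), bar length = fold
#' enrichment, fill = -log10 corrected p.
#'
#' @param object An `lfq_enrichment` tibble.
#' @param top_n Number of terms shown when no term is significant.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lfq_enrichment <- function(object, top_n = 10, ...) {
  df <- tidy(object)
  df <- if (any(df$significant)) df[df$significant, ] else head(df, top_n)
  df$term_id <- factor(df$term_id, levels = rev(df$term_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment,
                                   y = .data$term_id,
                                   fill = -log10(.data$q_value))) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "fold enrichment", y = NULL,
                  fill = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Scatter plot of transcript versus protein log2 fold changes
#'
#' The paired points behind a correlation result, faceted by functional
#' class (plus the pooled global panel), each panel annotated with its
#' Pearson r.
#'
#' @param object An `lfq_correlation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lfq_correlation <- function(object, ...) {
  pts <- correlation_points(object)
  res <- tidy(object)
  pts$scope <- ifelse(is.na(pts$functional_class), "unclassified",
                      pts$functional_class)
  pts <- bind_rows(pts, mutate(pts, scope = "global"))
  pts <- semi_join(pts, res, by = "scope")
  labels <- mutate(res, label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mrna_log2_ratio,
                                    y = .data$log2_ratio)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::geom_text(data = labels, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "mRNA log2 ratio", y = "protein log2 ratio") +
    ggplot2::theme_minimal()
}
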