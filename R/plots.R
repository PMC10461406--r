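#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_hline(yintercept = object$precision_target,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Plot PCA sample coordinates
#'
#' @param object A `profile_pca` from [pca_profiles()].
#' @param colour_by Optional named vector (by sample id) used for colour,
#'   e.g. species.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_pca <- function(object, colour_by = NULL, ...) {
  dat <- object$coords
  dat$group <- if (is.null(colour_by)) "samples" else
    colour_by[dat$sample_id]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                    colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of replicate correlations
#'
#' Tiles of pairwise Pearson correlations between sgRNA profiles, ordered by
#' the average-linkage clustering.
#'
#' @param object A `profile_correlation` from [replicate_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_correlation <- function(object, ...) {
  ord <- object$order
  dat <- as_tibble(as.data.frame.table(object$r, responseName = "r"))
  names(dat)[1:2] <- c("a", "b")
  dat$a <- factor(dat$a, levels = ord)
  dat$b <- factor(dat$b, levels = ord)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$a, y = .data$b,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Volcano-style plot of species-specific gene calls
#'
#' Gene LFC difference against contrast-term gene FDR, coloured by the final
#' call.
#'
#' @param object A `species_calls` table from [call_species_specific()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.species_calls <- function(object, ...) {
  thr <- attr(object, "thresholds")
  dat <- as_tibble(object)
  dat$signed_diff <- dat$lfc_b_gene - dat$lfc_a_gene
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$signed_diff,
                                    y = -log10(pmax(.data$fdr_diff, 1e-6)),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(thr$fdr), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Gene log2FC difference (B - A)",
                  y = "-log10 gene FDR", colour = NULL) +
    ggplot2::theme_minimal()
}
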