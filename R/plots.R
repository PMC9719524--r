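# ggplot2 autoplot methods.

#' Plot PCA sample scores
#'
#' @param object A `pop_pca` from [pca_scores()].
#' @param colour Optional vector (e.g. cluster or sex) to colour points by,
#'   aligned with the samples.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pop_pca
#' @export
autoplot.pop_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  df$colour <- if (is.null(colour)) "sample" else as.factor(colour)
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2, colour = .data$colour)) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
         colour = NULL) +
    theme_minimal()
  if (is.null(colour)) p <- p + theme(legend.position = "none")
  p
}

#' Heatmap of a pairwise Hamming distance matrix
#'
#' @param object A `hamming_dist` from [hamming_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hamming_dist
#' @export
autoplot.hamming_dist <- function(object, ...) {
  d <- object$d
  df <- tidyr::expand_grid(sample_a = rownames(d), sample_b = colnames(d))
  df$distance <- as.vector(t(d))
  ggplot(df, aes(x = .data$sample_a, y = .data$sample_b,
                 fill = .data$distance)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Hamming\ndistance") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Bar chart of reported sex-linked marker counts
#'
#' Mirrors the usual presentation: counts of XY- vs ZW-supporting SNP and
#' PA markers.
#'
#' @param object A `sexlink_scan` from [scan_sex_linked()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sexlink_scan
#' @export
autoplot.sexlink_scan <- function(object, ...) {
  df <- glance(object)
  if (!nrow(df)) {
    return(ggplot() +
             annotate("text", x = 0, y = 0, label = "no reported markers") +
             theme_void())
  }
  ggplot(df, aes(x = .data$marker_type, y = .data$n_markers,
                 fill = .data$system_call, alpha = .data$linkage_class)) +
    geom_col(position = "dodge") +
    scale_alpha_manual(values = c(PERFECT = 1, MODERATE = 0.6)) +
    labs(x = "marker type", y = "reported sex-linked markers",
         fill = "system", alpha = "linkage") +
    theme_minimal()
}

#' Scree-style plot of AMOVA variance components
#'
#' @param object An `amova_result` from [amova()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot amova_result
#' @export
autoplot.amova_result <- function(object, ...) {
  df <- dplyr::filter(object$table, .data$component != "total")
  df$component <- factor(df$component, levels = df$component)
  ggplot(df, aes(x = .data$component, y = .data$percent_variance)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "% of molecular variance") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 20, hjust = 1))
}
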