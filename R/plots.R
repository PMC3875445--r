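#' Stacked bar chart of library read-class composition
#'
#' @param composition Output of [summarize_composition()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  dat <- dplyr::filter(composition, .data$class != "mapped")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$library, y = .data$percent, fill = .data$class
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "% of total reads", fill = "read class",
      title = "Library composition"
    ) +
    ggplot2::theme_minimal()
}

#' Heat map of Z-scored abundances with UPGMA ordering
#'
#' Renders the numeric content of [cluster_profiles()]: a tile map of
#' row-scaled Z-scores with features and libraries ordered by their UPGMA
#' dendrograms.
#'
#' @param clustering A `heatmap_clustering` from [cluster_profiles()].
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(clustering) {
  stopifnot(inherits(clustering, "heatmap_clustering"))
  scaled <- clustering$scaled_rows
  long <- tidyr::pivot_longer(scaled, -"feature_id",
    names_to = "library", values_to = "z"
  )
  feat_order <- clustering$feature_dendrogram$labels[clustering$feature_dendrogram$order]
  lib_order <- clustering$library_dendrogram$labels[clustering$library_dendrogram$order]
  long$feature_id <- factor(long$feature_id, levels = feat_order)
  long$library <- factor(long$library, levels = lib_order)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$library, y = .data$feature_id, fill = .data$z
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Standard curves of a dilution-series fit
#'
#' @param object A `dilution_fits` object.
#' @param ... Unused.
#' @return A ggplot object, one facet per gene.
#' @export
autoplot.dilution_fits <- function(object, ...) {
  pts <- purrr::map_dfr(object$fits, function(f) {
    dplyr::mutate(f$model$model, gene_id = f$gene_id)
  })
  names(pts)[names(pts) == "log10(dilution)"] <- "log10_dilution"
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log10_dilution, y = .data$Ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = "log10 dilution", y = "Ct") +
    ggplot2::theme_minimal()
}

#' Bar chart of relative expression ratios with significance stars
#'
#' @param expression Output of [relative_expression()].
#' @return A ggplot object (log2 scale bars, stars above).
#' @export
plot_relative_expression <- function(expression) {
  ggplot2::ggplot(expression, ggplot2::aes(
    x = .data$gene_id, y = .data$ratio
  )) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$stars),
      vjust = -0.4
    ) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "treated / control ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
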