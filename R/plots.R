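#' Discriminant jitter plot
#'
#' One-dimensional LDA scores per event, jittered by class, visualizing
#' the degree of mixing between the two classes along the discriminant
#' axis.
#'
#' @param jitter Output of [jitter_data()].
#' @return A ggplot.
#' @export
plot_jitter <- function(jitter) {
  ggplot2::ggplot(jitter, ggplot2::aes(x = .data$class, y = .data$score,
                                       colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "LDA score",
                  subtitle = sprintf("overlap fraction: %.3f",
                                     attr(jitter, "overlap"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' UMAP scatter plot
#'
#' @param embedding Output of [umap_embed()].
#' @param colour Annotation column mapped to colour (default `"class"`).
#' @return A ggplot.
#' @export
plot_umap <- function(embedding, colour = "class") {
  ggplot2::ggplot(embedding,
                  ggplot2::aes(x = .data$umap1, y = .data$umap2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = colour) +
    ggplot2::theme_minimal()
}

#' Correlation-map heatmap
#'
#' @param cmap A [correlation_map()].
#' @return A ggplot raster of the Pearson coefficients.
#' @export
plot_correlation_map <- function(cmap) {
  stopifnot(inherits(cmap, "correlation_map"))
  df <- tidyr::expand_grid(i = seq_len(nrow(cmap$r)),
                           j = seq_len(ncol(cmap$r)))
  df$r <- as.vector(cmap$r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "feature (1 Da bins)", y = "feature (1 Da bins)",
                  fill = "Pearson r", subtitle = cmap$tag) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cv_report <- function(object, ...) {
  df <- object$per_fold %>%
    tidyr::pivot_longer(c("acc_classifiable", "acc_all"),
                        names_to = "denominator", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold),
                                   y = .data$accuracy,
                                   fill = .data$denominator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fold", y = "accuracy (%)", fill = NULL) +
    ggplot2::scale_fill_discrete(labels = c(acc_all = "per all points",
                                            acc_classifiable =
                                              "per classifiable")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rejection_lda <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centre, y = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$centre - object$sd_threshold * .data$sd,
      xmax = .data$centre + object$sd_threshold * .data$sd),
      height = 0.15) +
    ggplot2::labs(x = "LDA score", y = NULL,
                  subtitle = sprintf("centres +/- %g SD rejection radius",
                                     object$sd_threshold)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
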