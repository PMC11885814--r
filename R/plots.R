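# ggplot2 visualization methods for result objects

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, color = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decision_surface <- function(object, data = NULL, ...) {
  f <- setdiff(names(object), "label")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[f[1]]], y = .data[[f[2]]],
                                    fill = .data$label)) +
    ggplot2::geom_raster(alpha = 0.5) +
    ggplot2::labs(title = sprintf("%s decision surface", toupper(attr(object, "kind")))) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data[[f[1]]], y = .data[[f[2]]],
                   color = .data$label),
      inherit.aes = FALSE, size = 0.8)
  }
  p
}

#' @export
autoplot.tsne_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$label)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(title = sprintf("Latent-space t-SNE (overlap %.3f)",
                                  attr(object, "overlap")),
                  x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.transit_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("x", "DI", "v")],
                              cols = c("DI", "v"), names_to = "quantity")
  pl <- constriction_planes(attr(object, "geometry"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_vline(xintercept = unname(pl), linetype = "dotted") +
    ggplot2::geom_line(color = "#B2182B") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "cell center x (um)", y = NULL,
                  title = "Simulated transit: DI and velocity vs position") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.grad_cam_map <- function(object, alpha = 0.5, ...) {
  img <- attr(object, "image")
  df_img <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df_img$intensity <- as.vector(img)
  df_img$heat <- as.vector(unclass(object))
  ggplot2::ggplot(df_img, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$intensity), fill = "black") +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$heat), alpha = alpha) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::scale_alpha_continuous(range = c(1, 0), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Grad-CAM (%s layer)", attr(object, "layer")),
                  fill = "activation") +
    ggplot2::theme_minimal()
}

#' Training-history plot for any fitted model in the package
#'
#' @param fit A `miml_fit`, `image_classifier_fit` or `feature_nn_fit`.
#' @return A ggplot of train/validation accuracy per epoch.
#' @export
plot_training_history <- function(fit) {
  h <- tidy(fit)
  long <- tidyr::pivot_longer(h[, c("epoch", "train_acc", "val_acc")],
                              cols = -"epoch", names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "accuracy", color = NULL,
                  title = "Training and validation accuracy") +
    ggplot2::theme_minimal()
}

#' Write a grayscale matrix (or Grad-CAM overlay) to PNG
#'
#' @param img Matrix on the 0-255 or 0-1 scale.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  m <- unclass(img)
  if (max(m) > 1.5) m <- m / 255
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}
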