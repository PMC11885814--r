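# broom-style tidiers for fitted objects

#' @export
tidy.cv_results <- function(x, ...) x$per_fold

#' @export
glance.cv_results <- function(x, ...) {
  tibble(kind = x$kind, mean_accuracy = x$mean, sd_accuracy = x$sd,
         n_folds = nrow(x$per_fold))
}

#' @export
tidy.miml_fit <- function(x, ...) x$history

#' @export
glance.miml_fit <- function(x, ...) {
  h <- tail(x$history, 1)
  tibble(epochs = nrow(x$history), train_acc = h$train_acc,
         val_acc = h$val_acc, val_loss = h$val_loss,
         n_parameters = n_parameters(x$model))
}

#' @export
tidy.feature_nn_fit <- function(x, ...) x$history

#' @export
glance.feature_nn_fit <- function(x, ...) {
  h <- tail(x$history, 1)
  tibble(epochs = nrow(x$history), train_acc = h$train_acc,
         val_acc = h$val_acc, n_parameters = n_parameters(x$net))
}

#' @export
tidy.image_classifier_fit <- function(x, ...) x$history

#' @export
glance.image_classifier_fit <- function(x, ...) {
  h <- tail(x$history, 1)
  tibble(epochs = nrow(x$history), train_acc = h$train_acc,
         val_acc = h$val_acc, n_parameters = n_parameters(x$model))
}

#' @export
tidy.feature_stats <- function(x, ...) x$pairs

#' @export
glance.feature_stats <- function(x, ...) {
  out <- tibble(n = x$n, n_features = nrow(x$correlation))
  if (!is.null(x$welch_di)) {
    out$welch_t <- unname(x$welch_di$statistic)
    out$welch_p <- x$welch_di$p.value
  }
  out
}

#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(metric = c("accuracy", "precision", "recall", "f1"),
         value = c(x$accuracy, x$precision, x$recall, x$f1))
}
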