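#' Train the image-only residual classifier
#'
#' The single-modality baseline: the residual encoder with its fully
#' connected classification head, trained on the cell crops alone with the
#' same example convention as the fusion model (two images per cell;
#' cell-level validation accuracy averages the two image-level probability
#' vectors).
#'
#' @param dataset A `miml_dataset` with train/val splits.
#' @param config An [encoder_config()].
#' @param epochs,seed,lr,batch_size Training settings (Adam, cross-entropy).
#' @param keep `"best"` keeps the epoch with the highest validation
#'   accuracy; `"last"` the final state.
#' @param verbose Print per-epoch metrics.
#' @return An `image_classifier_fit` with `model`, `levels` and `history`.
#' @export
train_image_classifier <- function(dataset, config = encoder_config(),
                                   epochs = 40, seed = 42L, lr = 1e-3,
                                   batch_size = 32, keep = c("best", "last"),
                                   verbose = FALSE) {
  keep <- match.arg(keep)
  train <- dplyr::filter(dataset, .data$split == "train")
  val <- dplyr::filter(dataset, .data$split == "val")
  if (nrow(train) == 0 || nrow(val) == 0) {
    abort("dataset must contain both train and val splits")
  }
  levels_y <- levels(droplevels(factor(train$label)))
  ex_tr <- dataset_examples(train, character(0))
  ex_va <- dataset_examples(val, character(0))
  ytr <- match(as.character(ex_tr$label), levels_y)

  set.seed(seed)
  enc <- build_encoder(config, n_classes = length(levels_y),
                       seed = derive_seed(seed, 21))
  flat <- flatten_params(unclass(enc))
  opt <- adam_init(flat)
  history <- list()
  best <- list(acc = -Inf, model = enc, epoch = 0L)
  n <- nrow(ex_tr)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0; tr_hits <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1, n)]
      xb <- batch_images(ex_tr$image[ix], config)
      fw <- encoder_fw(enc, xb, training = TRUE, with_head = TRUE)
      enc <- fw$enc
      probs <- softmax_cols(fw$logits)
      tr_loss <- tr_loss + cross_entropy(probs, ytr[ix]); nb <- nb + 1
      tr_hits <- tr_hits + sum(apply(probs, 2, which.max) == ytr[ix])
      bw <- encoder_bw(enc, fw$cache, dlogits = ce_grad(probs, ytr[ix]))
      st <- adam_step(flat, bw$grads, opt, lr)
      flat <- st$flat; opt <- st$state
      enc <- assign_params(enc, flat)
    }
    va <- eval_cells(function(imgs, m) {
      xb <- batch_images(imgs, config)
      softmax_cols(encoder_fw(enc, xb, training = FALSE, with_head = TRUE)$logits)
    }, ex_va, matrix(0, 0, nrow(ex_va)), levels_y, batch_size = batch_size)
    history[[ep]] <- tibble(epoch = ep, train_loss = tr_loss / nb,
                            train_acc = tr_hits / n, val_loss = va$loss,
                            val_acc = va$acc)
    if (va$acc > best$acc) best <- list(acc = va$acc, model = enc, epoch = ep)
    if (verbose) {
      message(sprintf("epoch %d: train acc %.3f | val acc %.3f",
                      ep, tr_hits / n, va$acc))
    }
  }
  structure(list(model = if (keep == "best") best$model else enc,
                 levels = levels_y, history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, seed = seed),
            class = "image_classifier_fit")
}

#' @export
print.image_classifier_fit <- function(x, ...) {
  h <- tail(x$history, 1)
  cat(sprintf("<image_classifier_fit> %d epochs; val accuracy %.3f\n",
              nrow(x$history), h$val_acc))
  invisible(x)
}

#' @export
predict.image_classifier_fit <- function(object, newdata,
                                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  ex <- dataset_examples(newdata, character(0))
  cfg <- object$model$cfg
  va <- eval_cells(function(imgs, m) {
    xb <- batch_images(imgs, cfg)
    softmax_cols(encoder_fw(object$model, xb, FALSE, TRUE)$logits)
  }, ex, matrix(0, 0, nrow(ex)), object$levels)
  pred <- factor(object$levels[apply(va$probs, 1, which.max)],
                 levels = object$levels)
  if (type == "class") return(pred)
  out <- as_tibble(va$probs, .name_repair = "minimal")
  names(out) <- object$levels
  dplyr::bind_cols(va$cells, out, tibble(.pred = pred))
}
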