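#' Fusion-head configuration
#'
#' The multimodal head concatenates the image latent `z1` (width `n_cnn`,
#' set by the encoder) with the feature-branch latent `z2` (width `n_mlp`)
#' into `u`, then applies Linear -> BatchNorm -> ReLU to width `h2`, the
#' same to width `h3`, and a final linear + softmax over `n_classes`.
#' By default `z2` is the 16-wide penultimate activation of the feature
#' network; `fuse = "logits"` instead fuses the feature network's class
#' logits.
#'
#' @param n_mlp Feature-branch latent width (must match the feature
#'   network's penultimate width, or its class count under logit fusion).
#' @param h2,h3 Head widths.
#' @param n_classes Output classes.
#' @param fuse `"latent"` or `"logits"`.
#' @return A `fusion_config`.
#' @export
fusion_config <- function(n_mlp = 16, h2 = 128, h3 = 32, n_classes = 2,
                          fuse = c("latent", "logits")) {
  fuse <- match.arg(fuse)
  stopifnot(h2 > h3, h3 >= n_classes)
  structure(list(n_mlp = as.integer(n_mlp), h2 = as.integer(h2),
                 h3 = as.integer(h3), n_classes = as.integer(n_classes),
                 fuse = fuse),
            class = "fusion_config")
}

#' Full multimodal model configuration
#'
#' @param encoder An [encoder_config()].
#' @param feature_nn A [feature_nn_config()].
#' @param fusion A [fusion_config()].
#' @param features Which feature columns feed the feature branch.
#' @return A `miml_config`.
#' @export
miml_config <- function(encoder = encoder_config(),
                        feature_nn = feature_nn_config(),
                        fusion = fusion_config(),
                        features = c("DI", "TT", "vmax")) {
  if (feature_nn$input_dim != length(features)) {
    abort("feature_nn input_dim must match the number of feature columns")
  }
  expected <- if (fusion$fuse == "latent") feature_nn$hidden[2] else feature_nn$n_classes
  if (fusion$n_mlp != expected) {
    abort(sprintf("fusion n_mlp (%d) must match the feature branch latent width (%d)",
                  fusion$n_mlp, expected))
  }
  structure(list(encoder = encoder, feature_nn = feature_nn, fusion = fusion,
                 features = features),
            class = "miml_config")
}

#' Build an untrained multimodal fusion model
#'
#' @param config A [miml_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `miml_model` with components `encoder`, `feature_nn` and the
#'   fusion `head`; the fused width is `n_cnn + n_mlp`.
#' @export
build_miml <- function(config = miml_config(), seed = 1L) {
  n_cnn <- config$encoder$filters[config$encoder$n_stages]
  u_width <- n_cnn + config$fusion$n_mlp
  with_seed(seed, {
    structure(
      list(cfg = config,
           n_cnn = n_cnn, u_width = u_width,
           encoder = build_encoder(config$encoder,
                                   n_classes = config$fusion$n_classes,
                                   seed = derive_seed(seed, 11)),
           feature_nn = build_feature_nn(config$feature_nn,
                                         seed = derive_seed(seed, 12)),
           head = list(l1 = nn_linear(u_width, config$fusion$h2),
                       bn1 = nn_bn(config$fusion$h2),
                       l2 = nn_linear(config$fusion$h2, config$fusion$h3),
                       bn2 = nn_bn(config$fusion$h3),
                       l3 = nn_linear(config$fusion$h3, config$fusion$n_classes,
                                      scale = 0.01))),
      class = "miml_model"
    )
  })
}

#' @export
print.miml_model <- function(x, ...) {
  cat(sprintf("<miml_model> z1 %d + z2 %d -> u %d -> %d -> %d -> %d classes (%s fusion)\n",
              x$n_cnn, x$cfg$fusion$n_mlp, x$u_width, x$cfg$fusion$h2,
              x$cfg$fusion$h3, x$cfg$fusion$n_classes, x$cfg$fusion$fuse))
  invisible(x)
}

miml_fw <- function(model, x_img, m, training = FALSE, keep_cache = FALSE) {
  ef <- encoder_fw(model$encoder, x_img, training = training, with_head = FALSE)
  model$encoder <- ef$enc
  ff <- feature_nn_forward(model$feature_nn, m, keep_cache = keep_cache)
  z2 <- if (model$cfg$fusion$fuse == "latent") ff$penultimate else ff$logits
  if (nrow(z2) != model$cfg$fusion$n_mlp) {
    abort("feature-branch latent width does not match the fusion config")
  }
  u <- rbind(ef$z, z2)
  h <- model$head
  f1 <- linear_fw(h$l1, u)
  b1 <- bn1d_fw(h$bn1, f1$y, training)
  model$head$bn1 <- b1$layer
  r1 <- relu_fw(b1$y)
  f2 <- linear_fw(h$l2, r1$y)
  b2 <- bn1d_fw(h$bn2, f2$y, training)
  model$head$bn2 <- b2$layer
  r2 <- relu_fw(b2$y)
  f3 <- linear_fw(h$l3, r2$y)
  probs <- softmax_cols(f3$y)
  cache <- if (keep_cache) {
    list(enc = ef$cache, feat = ff$cache, f1 = f1$cache, b1 = b1$cache,
         r1 = r1$cache, f2 = f2$cache, b2 = b2$cache, r2 = r2$cache,
         f3 = f3$cache)
  }
  list(probs = probs, logits = f3$y, u = u, z1 = ef$z, z2 = z2,
       stage_acts = ef$stage_acts, cache = cache, model = model)
}

miml_bw <- function(model, cache, dlogits, stop_at_stage = NULL) {
  h <- model$head
  g <- list()
  l3 <- linear_bw(h$l3, cache$f3, dlogits)
  g <- merge_grads(g, prefix_grads(l3$grads, "head.l3"))
  dr2 <- relu_bw(cache$r2, l3$dx)
  b2 <- bn1d_bw(h$bn2, cache$b2, dr2)
  g <- merge_grads(g, prefix_grads(b2$grads, "head.bn2"))
  l2 <- linear_bw(h$l2, cache$f2, b2$dx)
  g <- merge_grads(g, prefix_grads(l2$grads, "head.l2"))
  dr1 <- relu_bw(cache$r1, l2$dx)
  b1 <- bn1d_bw(h$bn1, cache$b1, dr1)
  g <- merge_grads(g, prefix_grads(b1$grads, "head.bn1"))
  l1 <- linear_bw(h$l1, cache$f1, b1$dx)
  g <- merge_grads(g, prefix_grads(l1$grads, "head.l1"))
  du <- l1$dx
  dz1 <- du[seq_len(model$n_cnn), , drop = FALSE]
  dz2 <- du[model$n_cnn + seq_len(model$cfg$fusion$n_mlp), , drop = FALSE]
  eb <- encoder_bw(model$encoder, cache$enc, dz = dz1,
                   stop_at_stage = stop_at_stage)
  g <- merge_grads(g, prefix_grads(eb$grads, "encoder"))
  fb <- if (model$cfg$fusion$fuse == "latent") {
    feature_nn_bw(model$feature_nn, cache$feat, dpenult = dz2)
  } else {
    feature_nn_bw(model$feature_nn, cache$feat, dlogits = dz2)
  }
  g <- merge_grads(g, prefix_grads(fb$grads, "feature_nn"))
  list(grads = g, d_stage = eb$d_stage)
}

#' Forward pass of the fusion model
#'
#' Evaluation-mode prediction `y = F_MIML(x)` for inputs `x = (I, m)`.
#'
#' @param model A `miml_model` (or the `model` inside a `miml_fit`).
#' @param images A list of crop matrices, a single matrix, or an
#'   `H x W x C x N` array.
#' @param features Feature matrix (`d x N`), data frame of feature columns,
#'   or a single feature vector. Must already be normalized to \[0, 1\].
#' @return Matrix of class probabilities, `n_classes x N`.
#' @export
forward_miml <- function(model, images, features) {
  stopifnot(inherits(model, "miml_model"))
  x <- as_image_batch(images, model$cfg$encoder)
  if (is.data.frame(features)) features <- t(as.matrix(features))
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  if (ncol(features) != dim(x)[4]) {
    abort("number of images and feature vectors must agree")
  }
  miml_fw(model, x, features, training = FALSE)$probs
}

# ---- training ---------------------------------------------------------------

# Example-level view of a dataset: each cell contributes its two images as
# independent examples sharing the cell's feature vector.
dataset_examples <- function(dataset, features) {
  missing_img <- vapply(seq_len(nrow(dataset)), function(i) {
    is.null(dataset$image_entry[[i]]) || is.null(dataset$image_exit[[i]])
  }, TRUE)
  missing_feat <- if (length(features)) !stats::complete.cases(dataset[features]) else
    rep(FALSE, nrow(dataset))
  if (any(missing_img | missing_feat)) {
    abort(paste0("records missing a modality: ",
                 paste(dataset$cell_id[missing_img | missing_feat], collapse = ", ")))
  }
  tibble(
    cell_id = rep(dataset$cell_id, each = 2),
    label = rep(dataset$label, each = 2),
    split = rep(dataset$split, each = 2),
    image = unlist(lapply(seq_len(nrow(dataset)), function(i) {
      list(dataset$image_entry[[i]], dataset$image_exit[[i]])
    }), recursive = FALSE),
    feat_row = rep(seq_len(nrow(dataset)), each = 2))
}

batch_images <- function(img_list, cfg) {
  as_image_batch(img_list, cfg)
}

# cell-level evaluation: average the two image-level probability vectors
eval_cells <- function(forward, examples, xfeat, y_levels, batch_size = 64) {
  n <- nrow(examples)
  probs <- matrix(NA_real_, length(y_levels), n)
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    probs[, ix] <- forward(examples$image[ix], xfeat[, ix, drop = FALSE])
  }
  agg <- rowsum(t(probs), group = examples$cell_id) / 2
  cells <- examples[!duplicated(examples$cell_id),
                    c("cell_id", "label")]
  agg <- agg[match(cells$cell_id, rownames(agg)), , drop = FALSE]
  pred <- y_levels[apply(agg, 1, which.max)]
  loss <- -mean(log(pmax(agg[cbind(seq_len(nrow(agg)),
                                   match(cells$label, y_levels))], 1e-12)))
  list(acc = mean(pred == as.character(cells$label)), loss = loss,
       probs = agg, cells = cells)
}

#' Train the multimodal fusion model
#'
#' Minimizes cross-entropy over (image, feature, label) triples with Adam
#' (learning rate 1e-3, batch 32). Each cell's two images form independent
#' training examples sharing the cell's feature vector; validation accuracy
#' is cell-level (the two image-level probability vectors are averaged).
#' Mechanical features are min-max normalized with statistics from the
#' training split only.
#'
#' @param dataset A `miml_dataset` with train/val splits.
#' @param config A [miml_config()].
#' @param epochs Training epochs (the reference schedule is 40).
#' @param seed Integer seed controlling weight initialization and shuffling.
#' @param lr,batch_size Optimizer settings.
#' @param resume A previous `miml_fit` to continue training (restores
#'   weights, optimizer moments and the random-number state).
#' @param keep `"best"` returns the model from the epoch with the highest
#'   validation accuracy (standard checkpoint selection); `"last"` returns
#'   the final state (required for exact resuming).
#' @param encoder_lr_scale Multiplier on `lr` for encoder parameters
#'   (1 for joint training; 0.1 during transfer fine-tuning).
#' @param weight_decay Decoupled (AdamW-style) weight decay on weight
#'   matrices.
#' @param verbose Print per-epoch metrics.
#' @return A `miml_fit`: trained `model`, `normalizer`, label `levels`,
#'   per-epoch `history`, optimizer state and RNG state (for resuming).
#' @export
train_miml <- function(dataset, config = NULL, epochs = 40, seed = 42L,
                       lr = 1e-3, batch_size = 32, resume = NULL,
                       encoder_lr_scale = 1, weight_decay = 1e-4,
                       keep = c("best", "last"), verbose = FALSE) {
  keep <- match.arg(keep)
  if (is.null(config)) {
    config <- if (!is.null(resume)) resume$model$cfg else miml_config()
  }
  features <- config$features
  train <- dplyr::filter(dataset, .data$split == "train")
  val <- dplyr::filter(dataset, .data$split == "val")
  if (nrow(train) == 0 || nrow(val) == 0) {
    abort("dataset must contain both train and val splits")
  }
  norm <- if (!is.null(resume)) resume$normalizer else
    fit_normalizer(train, intersect(features, c("TT", "vmax", "DIR")))
  levels_y <- if (!is.null(resume)) resume$levels else
    levels(droplevels(factor(train$label)))

  ex_tr <- dataset_examples(train, features)
  ex_va <- dataset_examples(val, features)
  ftr <- t(as.matrix(apply_normalizer(train[features], norm)))
  fva <- t(as.matrix(apply_normalizer(val[features], norm)))
  xtr <- ftr[, ex_tr$feat_row, drop = FALSE]
  xva <- fva[, ex_va$feat_row, drop = FALSE]
  ytr <- match(as.character(ex_tr$label), levels_y)
  if (anyNA(ytr)) abort("training labels outside the model's class levels")

  if (!is.null(resume)) {
    model <- resume$model
    flat <- flatten_params(unclass(model))
    opt <- resume$opt
    history <- list(resume$history)
    ep0 <- max(resume$history$epoch)
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  } else {
    set.seed(seed)
    model <- build_miml(config, seed = derive_seed(seed, 7))
    flat <- flatten_params(unclass(model))
    opt <- adam_init(flat)
    history <- list()
    ep0 <- 0L
  }
  lr_scale <- NULL
  if (encoder_lr_scale != 1) {
    enc_names <- grep("^encoder\\.", names(flat), value = TRUE)
    lr_scale <- setNames(as.list(rep(encoder_lr_scale, length(enc_names))),
                         enc_names)
  }
  n <- nrow(ex_tr)
  best <- list(acc = -Inf, model = model, epoch = ep0)
  for (ep in seq_len(epochs) + ep0) {
    ord <- sample.int(n)
    tr_loss <- 0; tr_hits <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1, n)]
      xb <- batch_images(ex_tr$image[ix], config$encoder)
      fw <- miml_fw(model, xb, xtr[, ix, drop = FALSE], training = TRUE,
                    keep_cache = TRUE)
      model <- fw$model
      tr_loss <- tr_loss + cross_entropy(fw$probs, ytr[ix]); nb <- nb + 1
      tr_hits <- tr_hits + sum(apply(fw$probs, 2, which.max) == ytr[ix])
      bw <- miml_bw(model, fw$cache, ce_grad(fw$probs, ytr[ix]))
      st <- adam_step(flat, bw$grads, opt, lr, lr_scale = lr_scale,
                      weight_decay = weight_decay)
      flat <- st$flat; opt <- st$state
      model <- assign_params(model, flat)
    }
    va <- eval_cells(function(imgs, m) {
      forward_miml(model, imgs, as.data.frame(t(m)))
    }, ex_va, xva, levels_y, batch_size = batch_size)
    history[[length(history) + 1]] <- tibble(
      epoch = ep, train_loss = tr_loss / nb, train_acc = tr_hits / n,
      val_loss = va$loss, val_acc = va$acc)
    if (va$acc > best$acc) best <- list(acc = va$acc, model = model, epoch = ep)
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      ep, tr_loss / nb, tr_hits / n, va$loss, va$acc))
    }
  }
  structure(
    list(model = if (keep == "best") best$model else model,
         normalizer = norm, levels = levels_y,
         history = dplyr::bind_rows(history),
         best_epoch = best$epoch, seed = seed, opt = opt,
         rng_state = get(".Random.seed", envir = globalenv())),
    class = "miml_fit"
  )
}

#' @export
print.miml_fit <- function(x, ...) {
  h <- tail(x$history, 1)
  cat(sprintf("<miml_fit> %d epochs; val accuracy %.3f; classes: %s\n",
              nrow(x$history), h$val_acc, paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict cell classes with a trained fusion model
#'
#' Cell-level predictions: the two image-level probability vectors of each
#' cell are averaged.
#'
#' @param object A `miml_fit`.
#' @param newdata A `miml_dataset`.
#' @param type `"prob"` for class probabilities or `"class"`.
#' @param ... Unused.
#' @return A tibble with `cell_id`, `label`, one probability column per
#'   class, and the predicted class `.pred`.
#' @export
predict.miml_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  features <- object$model$cfg$features
  ex <- dataset_examples(newdata, features)
  f <- t(as.matrix(apply_normalizer(newdata[features], object$normalizer)))
  xf <- f[, ex$feat_row, drop = FALSE]
  va <- eval_cells(function(imgs, m) {
    forward_miml(object$model, imgs, as.data.frame(t(m)))
  }, ex, xf, object$levels)
  pred <- factor(object$levels[apply(va$probs, 1, which.max)],
                 levels = object$levels)
  if (type == "class") return(pred)
  out <- as_tibble(va$probs, .name_repair = "minimal")
  names(out) <- object$levels
  dplyr::bind_cols(va$cells, out, tibble(.pred = pred))
}

#' Latent embeddings of a dataset under a trained model
#'
#' @param fit A `miml_fit` or `image_classifier_fit`.
#' @param dataset A `miml_dataset`.
#' @param space `"fused"` for the concatenated `u` vector, `"image"` for the
#'   encoder latent `z1` alone.
#' @return List with `embeddings` (N_examples x width), `labels` and
#'   `cell_id` aligned to rows.
#' @export
miml_latent <- function(fit, dataset, space = c("fused", "image")) {
  space <- match.arg(space)
  model <- fit$model
  features <- model$cfg$features
  ex <- dataset_examples(dataset, features)
  f <- t(as.matrix(apply_normalizer(dataset[features], fit$normalizer)))
  xf <- f[, ex$feat_row, drop = FALSE]
  n <- nrow(ex)
  out <- NULL
  for (start in seq(1, n, by = 64)) {
    ix <- start:min(start + 63, n)
    xb <- batch_images(ex$image[ix], model$cfg$encoder)
    fw <- miml_fw(model, xb, xf[, ix, drop = FALSE], training = FALSE)
    block <- if (space == "fused") fw$u else fw$z1
    out <- rbind(out, t(block))
  }
  list(embeddings = out, labels = ex$label, cell_id = ex$cell_id)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all weights, the encoder,
#' feature-network and fusion configurations, the normalization statistics,
#' optimizer state and RNG state, so training can resume exactly.
#'
#' @param fit A `miml_fit`.
#' @param path File path.
#' @return `load_checkpoint` returns the `miml_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "miml_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "miml_fit"))
  fit
}

#' Transfer a trained fusion model to a new task
#'
#' Loads all transferable weights from a checkpoint; when the new task's
#' class count differs, the final classification layer is re-initialized to
#' the new count. The whole model is then fine-tuned end-to-end with the
#' encoder at a tenfold reduced learning rate.
#'
#' @param checkpoint A `miml_fit` or a path to one.
#' @param new_dataset A `miml_dataset` for the new task.
#' @param epochs Fine-tuning epochs (the reference schedule is 30).
#' @param seed Integer seed.
#' @param lr Base learning rate for the head and feature branch.
#' @param weight_decay Decoupled weight decay; stronger by default than in
#'   joint training because fine-tuning sets see far fewer examples.
#' @return A `miml_fit` on the new task.
#' @export
miml_transfer <- function(checkpoint, new_dataset, epochs = 30, seed = 1L,
                          lr = 1e-3, weight_decay = 1e-2) {
  fit <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  stopifnot(inherits(fit, "miml_fit"))
  new_levels <- levels(droplevels(factor(new_dataset$label)))
  model <- fit$model
  if (length(new_levels) != length(fit$levels)) {
    cfg <- model$cfg
    cfg$fusion$n_classes <- length(new_levels)
    with_seed(derive_seed(seed, 3), {
      model$head$l3 <- nn_linear(cfg$fusion$h3, cfg$fusion$n_classes,
                                  scale = 0.01)
    })
    model$cfg <- cfg
  }
  train <- dplyr::filter(new_dataset, .data$split == "train")
  norm <- fit_normalizer(train, intersect(model$cfg$features,
                                          c("TT", "vmax", "DIR")))
  warm <- structure(
    list(model = model, normalizer = norm, levels = new_levels,
         history = tibble(epoch = 0L, train_loss = NA_real_,
                          train_acc = NA_real_, val_loss = NA_real_,
                          val_acc = NA_real_),
         seed = seed, opt = adam_init(flatten_params(unclass(model))),
         rng_state = with_seed(seed, get(".Random.seed", envir = globalenv()))),
    class = "miml_fit")
  out <- train_miml(new_dataset, config = model$cfg, epochs = epochs,
                    seed = seed, lr = lr, resume = warm,
                    encoder_lr_scale = 0.1, weight_decay = weight_decay)
  out$history <- dplyr::filter(out$history, .data$epoch > 0)
  out
}
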