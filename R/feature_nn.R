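#' Feature-network configuration
#'
#' The small fully connected network operating on the mechanical feature
#' vector alone: `d -> 32 -> 16 -> n_classes` with ReLU activations on the
#' hidden layers and a softmax output. With the defaults (`d = 3`,
#' `n_classes = 2`) it has 690 trainable parameters. The 16-wide penultimate
#' activation doubles as the feature-branch latent `z2` in the fusion model.
#'
#' @param input_dim Feature dimensionality `d` (3, or 4 when DIR is used).
#' @param hidden Hidden-layer widths.
#' @param n_classes Number of output classes.
#' @return A `feature_nn_config`.
#' @export
feature_nn_config <- function(input_dim = 3, hidden = c(32, 16), n_classes = 2) {
  stopifnot(length(hidden) == 2, all(hidden > 0), n_classes >= 2)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 n_classes = as.integer(n_classes)),
            class = "feature_nn_config")
}

#' Build an untrained feature network
#'
#' @param config A [feature_nn_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `feature_nn`.
#' @export
build_feature_nn <- function(config = feature_nn_config(), seed = 1L) {
  with_seed(seed, {
    structure(
      list(cfg = config,
           l1 = nn_linear(config$input_dim, config$hidden[1]),
           l2 = nn_linear(config$hidden[1], config$hidden[2]),
           l3 = nn_linear(config$hidden[2], config$n_classes)),
      class = "feature_nn"
    )
  })
}

#' Forward pass of the feature network
#'
#' @param net A `feature_nn`.
#' @param m Feature matrix, `d x N` (a single feature vector is accepted).
#' @param keep_cache Keep the intermediate activations for backprop.
#' @return List with `probs` (`n_classes x N` softmax probabilities),
#'   `penultimate` (the 16-wide hidden activation), `logits`, and `cache`.
#' @export
feature_nn_forward <- function(net, m, keep_cache = FALSE) {
  if (is.vector(m)) m <- matrix(m, ncol = 1)
  if (nrow(m) != net$cfg$input_dim) {
    abort(sprintf("feature dimensionality %d does not match network input_dim %d",
                  nrow(m), net$cfg$input_dim))
  }
  f1 <- linear_fw(net$l1, m)
  r1 <- relu_fw(f1$y)
  f2 <- linear_fw(net$l2, r1$y)
  r2 <- relu_fw(f2$y)
  f3 <- linear_fw(net$l3, r2$y)
  probs <- softmax_cols(f3$y)
  cache <- if (keep_cache) {
    list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache, r2 = r2$cache,
         f3 = f3$cache)
  }
  list(probs = probs, penultimate = r2$y, logits = f3$y, cache = cache)
}

# Backward from gradients on logits and/or on the penultimate activation.
feature_nn_bw <- function(net, cache, dlogits = NULL, dpenult = NULL) {
  g <- list()
  dr2 <- dpenult
  if (!is.null(dlogits)) {
    l3 <- linear_bw(net$l3, cache$f3, dlogits)
    g <- merge_grads(g, prefix_grads(l3$grads, "l3"))
    dr2 <- if (is.null(dr2)) l3$dx else dr2 + l3$dx
  }
  df2 <- relu_bw(cache$r2, dr2)
  l2 <- linear_bw(net$l2, cache$f2, df2)
  g <- merge_grads(g, prefix_grads(l2$grads, "l2"))
  df1 <- relu_bw(cache$r1, l2$dx)
  l1 <- linear_bw(net$l1, cache$f1, df1)
  g <- merge_grads(g, prefix_grads(l1$grads, "l1"))
  list(dx = l1$dx, grads = g)
}

#' Train the feature network on a labelled feature table
#'
#' Minimizes cross-entropy with Adam (learning rate 1e-3, batch 32) with
#' early stopping on validation loss. Features are min-max normalized with
#' statistics fitted on the training rows only (DI passes through).
#'
#' @param data Tibble with the feature columns, a `label` factor, and a
#'   `split` column (`train` / `val`); alternatively pass `val` explicitly.
#' @param features Feature columns to use (their number must match the
#'   configured `input_dim`).
#' @param config A [feature_nn_config()].
#' @param epochs Maximum epochs.
#' @param seed Integer seed (weights and shuffling).
#' @param lr,batch_size,patience Optimizer settings.
#' @param val Optional validation tibble (otherwise `split == "val"`).
#' @return A `feature_nn_fit`: the network, the normalizer, label levels and
#'   a per-epoch `history` tibble.
#' @export
train_feature_nn <- function(data, features = c("DI", "TT", "vmax"),
                             config = NULL, epochs = 100, seed = 1L,
                             lr = 1e-3, batch_size = 32, patience = 10,
                             val = NULL) {
  if (is.null(val)) {
    stopifnot("split" %in% names(data))
    val <- dplyr::filter(data, .data$split == "val")
    data <- dplyr::filter(data, .data$split == "train")
  }
  labels <- droplevels(factor(data$label))
  if (is.null(config)) {
    config <- feature_nn_config(input_dim = length(features),
                                n_classes = nlevels(labels))
  }
  if (config$input_dim != length(features)) {
    abort("length(features) must equal the configured input_dim")
  }
  norm <- fit_normalizer(data, intersect(features, c("TT", "vmax", "DIR")))
  xtr <- t(as.matrix(apply_normalizer(data[features], norm)))
  ytr <- as.integer(labels)
  xva <- t(as.matrix(apply_normalizer(val[features], norm)))
  yva <- as.integer(factor(val$label, levels = levels(labels)))

  with_seed(seed, {
    net <- build_feature_nn(config, seed = derive_seed(seed, 1))
    flat <- flatten_params(unclass(net))
    opt <- adam_init(flat)
    history <- list()
    best <- list(loss = Inf, net = net, epoch = 0L)
    n <- ncol(xtr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1, n)]
        fw <- feature_nn_forward(net, xtr[, ix, drop = FALSE], keep_cache = TRUE)
        tr_loss <- tr_loss + cross_entropy(fw$probs, ytr[ix]); nb <- nb + 1
        bw <- feature_nn_bw(net, fw$cache, dlogits = ce_grad(fw$probs, ytr[ix]))
        st <- adam_step(flat, bw$grads, opt, lr)
        flat <- st$flat; opt <- st$state
        net <- assign_params(net, flat)
      }
      fw_tr <- feature_nn_forward(net, xtr)
      fw_va <- feature_nn_forward(net, xva)
      va_loss <- cross_entropy(fw_va$probs, yva)
      history[[ep]] <- tibble(
        epoch = ep, train_loss = cross_entropy(fw_tr$probs, ytr),
        val_loss = va_loss,
        train_acc = mean(apply(fw_tr$probs, 2, which.max) == ytr),
        val_acc = mean(apply(fw_va$probs, 2, which.max) == yva))
      if (va_loss < best$loss - 1e-6) {
        best <- list(loss = va_loss, net = net, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
    structure(
      list(net = best$net, normalizer = norm, features = features,
           levels = levels(labels), history = dplyr::bind_rows(history),
           seed = seed),
      class = "feature_nn_fit"
    )
  })
}

#' @export
predict.feature_nn_fit <- function(object, newdata, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  x <- t(as.matrix(apply_normalizer(newdata[object$features], object$normalizer)))
  probs <- feature_nn_forward(object$net, x)$probs
  if (type == "class") {
    factor(object$levels[apply(probs, 2, which.max)], levels = object$levels)
  } else {
    out <- as_tibble(t(probs), .name_repair = "minimal")
    names(out) <- object$levels
    out
  }
}

#' @export
print.feature_nn_fit <- function(x, ...) {
  h <- tail(x$history, 1)
  cat(sprintf("<feature_nn_fit> d=%d -> %s -> %d classes; %d params; val acc %.3f\n",
              x$net$cfg$input_dim, paste(x$net$cfg$hidden, collapse = "/"),
              x$net$cfg$n_classes, n_parameters(x$net), h$val_acc))
  invisible(x)
}
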