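#' Image-encoder configuration
#'
#' An 18-layer-style residual encoder: a 7x7 stride-2 convolution with batch
#' normalization, ReLU and 3x3 stride-2 max pooling, followed by four stages
#' of two residual blocks each, with the filter count doubling at every
#' stage starting from `base_filters`. Stages 2-4 downsample with a stride-2
#' first convolution and a 1x1 projection shortcut. A global average pool
#' yields the latent embedding; the final fully connected layer is used in
#' classifier mode and replaced by an identity when the encoder feeds the
#' fusion model.
#'
#' @param in_channels Input channels C (grayscale crops are replicated to 3).
#' @param input_size Integer `c(H, W)`; both must be at least 32 so the five
#'   downsamplings stay well defined.
#' @param base_filters Filters in the first stage (64 for the reference
#'   architecture; smaller values give desk-scale variants).
#' @param blocks_per_stage Residual blocks per stage.
#' @return An `encoder_config`.
#' @export
encoder_config <- function(in_channels = 3, input_size = c(64, 64),
                           base_filters = 64, blocks_per_stage = 2) {
  if (any(input_size < 32)) {
    abort("input_size must be at least 32 x 32 for 5 downsamplings")
  }
  structure(
    list(in_channels = as.integer(in_channels),
         input_size = as.integer(input_size),
         base_filters = as.integer(base_filters),
         blocks_per_stage = as.integer(blocks_per_stage),
         n_stages = 4L,
         filters = as.integer(base_filters * 2^(0:3))),
    class = "encoder_config"
  )
}

res_block <- function(in_c, out_c, stride) {
  blk <- list(conv1 = nn_conv(in_c, out_c, 3L, stride = stride),
              bn1 = nn_bn(out_c),
              conv2 = nn_conv(out_c, out_c, 3L, stride = 1L),
              bn2 = nn_bn(out_c))
  if (stride != 1L || in_c != out_c) {
    blk$proj <- list(conv = nn_conv(in_c, out_c, 1L, stride = stride, pad = 0L),
                     bn = nn_bn(out_c))
  }
  blk
}

#' Build the residual image encoder
#'
#' @param config An [encoder_config()].
#' @param n_classes Classes for the classifier-mode head.
#' @param seed Integer seed for weight initialization.
#' @return A `miml_encoder` whose latent width is
#'   `config$base_filters * 8`.
#' @export
build_encoder <- function(config = encoder_config(), n_classes = 2, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  with_seed(seed, {
    stages <- vector("list", config$n_stages)
    in_c <- config$base_filters
    for (s in seq_len(config$n_stages)) {
      out_c <- config$filters[s]
      blocks <- vector("list", config$blocks_per_stage)
      for (b in seq_len(config$blocks_per_stage)) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        blocks[[b]] <- res_block(if (b == 1L) in_c else out_c, out_c, stride)
      }
      stages[[s]] <- blocks
      in_c <- out_c
    }
    structure(
      list(cfg = config,
           stem = list(conv = nn_conv(config$in_channels, config$base_filters,
                                      7L, stride = 2L, pad = 3L),
                       bn = nn_bn(config$base_filters)),
           stages = stages,
           fc = nn_linear(config$filters[config$n_stages], n_classes,
                          scale = 0.01)),
      class = "miml_encoder"
    )
  })
}

#' @export
print.miml_encoder <- function(x, ...) {
  cat(sprintf("<miml_encoder> %dx%dx%d -> stages [%s] x%d blocks -> latent %d\n",
              x$cfg$input_size[1], x$cfg$input_size[2], x$cfg$in_channels,
              paste(x$cfg$filters, collapse = ", "), x$cfg$blocks_per_stage,
              x$cfg$filters[4]))
  invisible(x)
}

block_fw <- function(blk, x, training) {
  c1 <- conv_fw_layer(blk$conv1, x)
  b1 <- bn_fw_layer(blk$bn1, c1$y, training)
  blk$bn1 <- b1$layer
  r1 <- relu_fw(b1$y)
  c2 <- conv_fw_layer(blk$conv2, r1$y)
  b2 <- bn_fw_layer(blk$bn2, c2$y, training)
  blk$bn2 <- b2$layer
  if (!is.null(blk$proj)) {
    pc <- conv_fw_layer(blk$proj$conv, x)
    pb <- bn_fw_layer(blk$proj$bn, pc$y, training)
    blk$proj$bn <- pb$layer
    sc <- pb$y
    proj_cache <- list(conv = pc$cache, bn = pb$cache)
  } else {
    sc <- x
    proj_cache <- NULL
  }
  ro <- relu_fw(b2$y + sc)
  list(y = ro$y, blk = blk,
       cache = list(conv1 = c1$cache, bn1 = b1$cache, relu1 = r1$cache,
                    conv2 = c2$cache, bn2 = b2$cache, proj = proj_cache,
                    relu_out = ro$cache))
}

block_bw <- function(blk, cache, dy) {
  dsum <- relu_bw(cache$relu_out, dy)
  g <- list()
  b2 <- bn_bw_layer(blk$bn2, cache$bn2, dsum)
  g <- merge_grads(g, prefix_grads(b2$grads, "bn2"))
  c2 <- conv_bw_layer(blk$conv2, cache$conv2, b2$dx)
  g <- merge_grads(g, prefix_grads(c2$grads, "conv2"))
  dr1 <- relu_bw(cache$relu1, c2$dx)
  b1 <- bn_bw_layer(blk$bn1, cache$bn1, dr1)
  g <- merge_grads(g, prefix_grads(b1$grads, "bn1"))
  c1 <- conv_bw_layer(blk$conv1, cache$conv1, b1$dx)
  g <- merge_grads(g, prefix_grads(c1$grads, "conv1"))
  dx <- c1$dx
  if (!is.null(blk$proj)) {
    pb <- bn_bw_layer(blk$proj$bn, cache$proj$bn, dsum)
    g <- merge_grads(g, prefix_grads(pb$grads, "proj.bn"))
    pc <- conv_bw_layer(blk$proj$conv, cache$proj$conv, pb$dx)
    g <- merge_grads(g, prefix_grads(pc$grads, "proj.conv"))
    dx <- dx + pc$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = g)
}

# Full forward pass. Returns the pooled latent (`z`, C x N), classifier
# logits, per-stage activations, the cache needed for backward, and the
# encoder with updated batch-norm running statistics.
encoder_fw <- function(enc, x, training = FALSE, with_head = TRUE) {
  stopifnot(length(dim(x)) == 4)
  if (!all(dim(x)[1:3] == c(enc$cfg$input_size, enc$cfg$in_channels))) {
    abort(sprintf("input shape %s does not match encoder config %s",
                  paste(dim(x)[1:3], collapse = "x"),
                  paste(c(enc$cfg$input_size, enc$cfg$in_channels), collapse = "x")))
  }
  cache <- list()
  sc <- conv_fw_layer(enc$stem$conv, x)
  sb <- bn_fw_layer(enc$stem$bn, sc$y, training)
  enc$stem$bn <- sb$layer
  sr <- relu_fw(sb$y)
  mp <- maxpool_fw(sr$y, 3L, 2L, 1L)
  cache$stem <- list(conv = sc$cache, bn = sb$cache, relu = sr$cache,
                     pool_idx = mp$idx, pool_xdim = dim(sr$y))
  h <- mp$y
  stage_acts <- vector("list", enc$cfg$n_stages)
  cache$stages <- vector("list", enc$cfg$n_stages)
  for (s in seq_along(enc$stages)) {
    cache$stages[[s]] <- vector("list", length(enc$stages[[s]]))
    for (b in seq_along(enc$stages[[s]])) {
      bf <- block_fw(enc$stages[[s]][[b]], h, training)
      enc$stages[[s]][[b]] <- bf$blk
      cache$stages[[s]][[b]] <- bf$cache
      h <- bf$y
    }
    stage_acts[[s]] <- h
  }
  gp <- gap_fw(h)
  cache$gap <- gp$cache
  z <- gp$y
  logits <- NULL
  if (with_head) {
    lf <- linear_fw(enc$fc, z)
    logits <- lf$y
    cache$fc <- lf$cache
  }
  list(z = z, logits = logits, stage_acts = stage_acts, cache = cache,
       enc = enc)
}

# Backward pass from a gradient on the latent (`dz`, C x N) and/or on the
# logits. If `stop_at_stage` is given, also returns the gradient w.r.t. that
# stage's output activation (used by Grad-CAM).
encoder_bw <- function(enc, cache, dz = NULL, dlogits = NULL,
                       stop_at_stage = NULL) {
  g <- list()
  if (!is.null(dlogits)) {
    lf <- linear_bw(enc$fc, cache$fc, dlogits)
    g <- merge_grads(g, prefix_grads(lf$grads, "fc"))
    dz <- if (is.null(dz)) lf$dx else dz + lf$dx
  }
  dh <- gap_bw(cache$gap, dz)
  d_stage <- NULL
  for (s in rev(seq_along(enc$stages))) {
    if (!is.null(stop_at_stage) && s == stop_at_stage) {
      d_stage <- dh
    }
    for (b in rev(seq_along(enc$stages[[s]]))) {
      bb <- block_bw(enc$stages[[s]][[b]], cache$stages[[s]][[b]], dh)
      g <- merge_grads(g, prefix_grads(bb$grads, sprintf("stages.%d.%d", s, b)))
      dh <- bb$dx
    }
  }
  dp <- maxpool_bw(dh, cache$stem$pool_idx, cache$stem$pool_xdim)
  dr <- relu_bw(cache$stem$relu, dp)
  sb <- bn_bw_layer(enc$stem$bn, cache$stem$bn, dr)
  g <- merge_grads(g, prefix_grads(sb$grads, "stem.bn"))
  sc <- conv_bw_layer(enc$stem$conv, cache$stem$conv, sb$dx)
  g <- merge_grads(g, prefix_grads(sc$grads, "stem.conv"))
  list(dx = sc$dx, grads = g, d_stage = d_stage)
}

#' Encode images into the latent space
#'
#' Runs the encoder in evaluation mode with the classification head bypassed
#' (identity mapping), returning the pooled high-dimensional embedding
#' `z1 = F_CNN(I)`.
#'
#' @param encoder A `miml_encoder`.
#' @param images A single H x W x C array, an H x W matrix (replicated to
#'   the configured channel count), or an H x W x C x N batch. Intensities
#'   on the 0-255 scale are rescaled to \[0, 1\].
#' @return A matrix of embeddings, latent width x N.
#' @export
encode_image <- function(encoder, images) {
  x <- as_image_batch(images, encoder$cfg)
  encoder_fw(encoder, x, training = FALSE, with_head = FALSE)$z
}

# Coerce user-supplied images to the (H, W, C, N) batch the encoder expects.
as_image_batch <- function(images, cfg) {
  if (is.list(images)) {
    x <- array(0, dim = c(cfg$input_size, cfg$in_channels, length(images)))
    for (i in seq_along(images)) {
      x[, , , i] <- as_image_batch(images[[i]], cfg)[, , , 1]
    }
    return(x)
  }
  if (is.matrix(images)) {
    images <- array(rep(images, cfg$in_channels),
                    dim = c(dim(images), cfg$in_channels))
  }
  if (length(dim(images)) == 3) {
    dim(images) <- c(dim(images), 1L)
  }
  if (!all(dim(images)[1:3] == c(cfg$input_size, cfg$in_channels))) {
    abort("image dimensions do not match the encoder configuration")
  }
  if (max(images, na.rm = TRUE) > 1.5) images <- images / 255
  # per-image standardization: recordings from different days vary in
  # illumination and camera gain, so absolute intensity is a nuisance
  d <- dim(images)
  m <- matrix(images, prod(d[1:3]), d[4])
  mu <- colMeans(m)
  sdv <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
  m <- sweep(sweep(m, 2, mu), 2, sdv + 1e-6, `/`)
  array(m, d)
}
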