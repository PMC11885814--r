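# Minimal neural-network toolkit backing the image encoder, the feature
# network and the fusion head. Layers are plain lists of parameter arrays;
# forward passes return caches, backward passes return gradients mirroring
# the parameter structure, and a generic Adam walks the flattened tree.
# Images and feature maps use R's column-major (H, W, C, N) layout.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

nn_conv <- function(in_c, out_c, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(kind = "conv",
       w = he_init(c(k, k, in_c, out_c), fan_in = k * k * in_c),
       b = numeric(out_c), stride = as.integer(stride), pad = as.integer(pad))
}

nn_bn <- function(c_out, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn", gamma = rep(1, c_out), beta = numeric(c_out),
       run_mean = numeric(c_out), run_var = rep(1, c_out),
       momentum = momentum, eps = eps)
}

nn_linear <- function(in_d, out_d, scale = NULL) {
  # classification output layers use a small init so an untrained model
  # predicts near-uniformly (initial loss ~ ln K)
  sdv <- if (is.null(scale)) sqrt(2 / in_d) else scale
  list(kind = "linear",
       w = matrix(rnorm(out_d * in_d, 0, sdv), out_d, in_d),
       b = numeric(out_d))
}

conv_fw_layer <- function(layer, x) {
  y <- conv2d_fw(x, layer$w, layer$b, layer$stride, layer$pad)
  list(y = y, cache = x)
}

conv_bw_layer <- function(layer, cache, dy) {
  g <- conv2d_bw(cache, layer$w, dy, layer$stride, layer$pad)
  list(dx = g$dx, grads = list(w = g$dw, b = g$db))
}

# Batch norm over (H, W, N) per channel. Works on 4-D arrays; for 2-D
# (features x N) input use bn1d_* below.
bn_fw_layer <- function(layer, x, training) {
  d <- dim(x)
  xp <- aperm(x, c(1, 2, 4, 3))
  dim(xp) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xp)
    v <- colMeans(xp^2) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xp, 2, mu), 2, inv, `*`)
  yp <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  dim(yp) <- c(d[1], d[2], d[4], d[3])
  y <- aperm(yp, c(1, 2, 4, 3))
  list(y = y, layer = layer,
       cache = list(xhat = xhat, inv = inv, dims = d, training = training))
}

bn_bw_layer <- function(layer, cache, dy) {
  d <- cache$dims
  dyp <- aperm(dy, c(1, 2, 4, 3))
  dim(dyp) <- c(d[1] * d[2] * d[4], d[3])
  m <- nrow(dyp)
  dgamma <- colSums(dyp * cache$xhat)
  dbeta <- colSums(dyp)
  if (cache$training) {
    dxhat <- sweep(dyp, 2, layer$gamma, `*`)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
    dxp <- sweep(t1 - t2, 2, cache$inv, `*`)
  } else {
    dxp <- sweep(sweep(dyp, 2, layer$gamma, `*`), 2, cache$inv, `*`)
  }
  dim(dxp) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxp, c(1, 2, 4, 3)),
       grads = list(gamma = dgamma, beta = dbeta))
}

bn1d_fw <- function(layer, x, training) {
  # x: features x N
  if (training && ncol(x) > 1) {
    mu <- rowMeans(x)
    v <- rowMeans(x^2) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    training <- FALSE
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- (x - mu) * inv
  y <- xhat * layer$gamma + layer$beta
  list(y = y, layer = layer,
       cache = list(xhat = xhat, inv = inv, training = training))
}

bn1d_bw <- function(layer, cache, dy) {
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  if (cache$training) {
    dxhat <- dy * layer$gamma
    dx <- (dxhat - rowMeans(dxhat) -
             cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$inv
  } else {
    dx <- dy * layer$gamma * cache$inv
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fw <- function(x) {
  y <- x * (x > 0)
  list(y = y, cache = x > 0)
}

relu_bw <- function(cache, dy) dy * cache

gap_fw <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- matrix(colMeans(xm), d[3], d[4])
  list(y = y, cache = d)
}

gap_bw <- function(cache, dy) {
  d <- cache
  dx <- array(rep(as.numeric(dy), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  dx
}

linear_fw <- function(layer, x) {
  list(y = layer$w %*% x + layer$b, cache = x)
}

linear_bw <- function(layer, cache, dy) {
  list(dx = crossprod(layer$w, dy),
       grads = list(w = tcrossprod(dy, cache), b = rowSums(dy)))
}

# Softmax probabilities (columns are examples) and cross-entropy loss.
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(y_idx, seq_along(y_idx))], 1e-12)))
}

ce_grad <- function(probs, y_idx) {
  d <- probs
  d[cbind(y_idx, seq_along(y_idx))] <- d[cbind(y_idx, seq_along(y_idx))] - 1
  d / length(y_idx)
}

# ---- parameter tree walking -------------------------------------------------

PARAM_NAMES <- c("w", "b", "gamma", "beta")

flatten_params <- function(node, path = character()) {
  out <- list()
  if (!is.list(node)) return(out)
  keys <- names(node)
  if (is.null(keys)) keys <- rep("", length(node))
  for (i in seq_along(node)) {
    nm <- if (nzchar(keys[i])) keys[i] else as.character(i)
    if (nm %in% PARAM_NAMES && is.numeric(node[[i]])) {
      out[[paste(c(path, nm), collapse = ".")]] <- node[[i]]
    } else if (is.list(node[[i]])) {
      out <- c(out, flatten_params(node[[i]], c(path, nm)))
    }
  }
  out
}

# path components that are all digits index positionally (unnamed lists)
path_key <- function(part) {
  if (grepl("^[0-9]+$", part)) as.integer(part) else part
}

set_param <- function(node, path_parts, value) {
  key <- path_key(path_parts[1])
  if (length(path_parts) == 1L) {
    dims <- dim(node[[key]])
    if (!is.null(dims)) dim(value) <- dims
    node[[key]] <- value
    return(node)
  }
  node[[key]] <- set_param(node[[key]], path_parts[-1], value)
  node
}

assign_params <- function(model, flat) {
  for (nm in names(flat)) {
    model <- set_param(model, strsplit(nm, ".", fixed = TRUE)[[1]], flat[[nm]])
  }
  model
}

#' Count trainable parameters of a network
#'
#' @param model A network object built by this package (feature network,
#'   encoder, image classifier or fusion model).
#' @return Integer number of trainable scalars.
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_params(unclass(model)), length, 0L))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, lr_scale = NULL, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- as.numeric(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    rate <- lr * if (!is.null(lr_scale) && !is.null(lr_scale[[nm]])) lr_scale[[nm]] else 1
    p <- as.numeric(flat[[nm]])
    # decoupled weight decay on weights only (not biases / norm parameters)
    if (weight_decay > 0 && grepl("\\.w$", nm)) p <- p * (1 - rate * weight_decay)
    flat[[nm]] <- p - rate * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# merge gradient trees (named flat lists) by addition
merge_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + as.numeric(b[[nm]])
  }
  a
}

# prefix every name in a flat gradient list
prefix_grads <- function(g, prefix) {
  if (!length(g)) return(g)
  names(g) <- paste(prefix, names(g), sep = ".")
  g
}
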