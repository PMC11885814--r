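#' Confusion counts from predictions
#'
#' @param truth,pred Factors (or vectors) of true and predicted labels.
#' @param positive The positive-class label (defaults to the second level).
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (is.null(positive)) positive <- sort(unique(truth))[length(unique(truth))]
  c(TP = sum(pred == positive & truth == positive),
    TN = sum(pred != positive & truth != positive),
    FP = sum(pred == positive & truth != positive),
    FN = sum(pred != positive & truth == positive))
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); Precision = TP/(TP+FP);
#' Recall = TP/(TP+FN); F1 = 2TP/(2TP+FP+FN). Ratios with a zero
#' denominator are reported as `NaN` and flagged.
#'
#' @param counts Named vector or list with `TP`, `TN`, `FP`, `FN` (all
#'   non-negative; total > 0).
#' @return A `metrics_report` list: the four metrics, the counts, and
#'   `undefined` naming any metric with a zero denominator.
#' @examples
#' compute_metrics(c(TP = 9, TN = 9, FP = 1, FN = 1))
#' @export
compute_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts)) abort("`counts` must provide TP, TN, FP and FN")
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) abort("confusion counts sum to zero")
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  ratio <- function(num, den) if (den == 0) NaN else num / den
  out <- list(accuracy = (tp + tn) / total,
              precision = ratio(tp, tp + fp),
              recall = ratio(tp, tp + fn),
              f1 = ratio(2 * tp, 2 * tp + fp + fn),
              confusion = counts)
  out$undefined <- names(which(vapply(out[1:4], is.nan, TRUE)))
  if (length(out$undefined)) {
    warn(paste("undefined metrics (zero denominator):",
               paste(out$undefined, collapse = ", ")))
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> acc %.4f  prec %.4f  rec %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; the AUC is the trapezoidal area,
#' so tied scores contribute diagonal segments and the value equals the
#' probability that a random positive is ranked above a random negative
#' (ties counted half).
#'
#' @param scores Positive-class scores or probabilities.
#' @param labels Binary labels; `positive` names the positive class.
#' @param positive Positive-class label (default: the larger level).
#' @return An `roc_curve` object: tibble of `(threshold, fpr, tpr)` from
#'   (0,0) to (1,1) plus an `auc` attribute (also `$auc`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) < 2) abort("both classes must be present to compute a ROC curve")
  if (length(u) > 2) abort("ROC curves are defined for binary labels")
  if (is.null(positive)) positive <- u[2]
  y <- labels == positive
  np <- sum(y); nn <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_last <- c(diff(ss) != 0, TRUE)
  tp <- cumsum(ys)[grp_last]
  fpc <- cumsum(!ys)[grp_last]
  curve <- tibble(threshold = c(Inf, ss[grp_last]),
                  fpr = c(0, fpc / nn), tpr = c(0, tp / np))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  out <- structure(curve, auc = auc, class = c("roc_curve", class(curve)))
  out$auc <- auc
  out
}

#' Feature correlation and regression statistics
#'
#' Pairwise Pearson correlations with two-sided p-values from the exact
#' t distribution on `n - 2` degrees of freedom; for each feature pair the
#' standardized simple-regression slope (whose magnitude equals |r|) with
#' its standard error `sqrt((1 - r^2) / (n - 2))`; class-conditional
#' mean/sd per feature; and a two-sample Welch t-test between the first two
#' classes on DI.
#'
#' @param table Feature table with a `label` column.
#' @param features Feature columns (default: the standard three plus DIR
#'   when present).
#' @param raw_slope Report raw (unstandardized) simple-regression slopes
#'   instead of standardized ones.
#' @return A `feature_stats` list: `correlation` and `p_value` matrices,
#'   a `pairs` tibble (`feature_x`, `feature_y`, `r`, `p`, `slope`, `se`),
#'   `class_stats`, and `welch_di` (the htest, when a label column with two
#'   or more classes is present).
#' @export
feature_statistics <- function(table, features = intersect(c("DI", "TT", "vmax", "DIR"),
                                                           names(table)),
                               raw_slope = FALSE) {
  x <- as.matrix(table[features])
  n <- nrow(x)
  if (n < 3) abort("need at least 3 rows")
  const <- features[apply(x, 2, function(v) diff(range(v)) == 0)]
  if (length(const)) {
    abort(paste("constant feature column(s):", paste(const, collapse = ", ")))
  }
  r <- cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  pairs_idx <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- tibble(
    feature_x = features[pairs_idx[, 1]],
    feature_y = features[pairs_idx[, 2]],
    r = r[pairs_idx],
    p = p[pairs_idx])
  if (raw_slope) {
    sds <- apply(x, 2, sd)
    pairs$slope <- unname(pairs$r * sds[pairs_idx[, 2]] / sds[pairs_idx[, 1]])
  } else {
    pairs$slope <- abs(pairs$r)
  }
  pairs$se <- sqrt((1 - pairs$r^2) / (n - 2))

  class_stats <- NULL
  welch <- NULL
  if ("label" %in% names(table)) {
    lab <- factor(table$label)
    class_stats <- dplyr::bind_rows(lapply(features, function(f) {
      agg <- tibble(label = levels(lab),
                    feature = f,
                    mean = tapply(table[[f]], lab, mean),
                    sd = tapply(table[[f]], lab, sd))
      agg
    }))
    if (nlevels(lab) >= 2 && "DI" %in% features) {
      l2 <- levels(lab)[1:2]
      welch <- t.test(table$DI[lab == l2[1]], table$DI[lab == l2[2]])
    }
  }
  structure(list(correlation = r, p_value = p, pairs = pairs,
                 class_stats = class_stats, welch_di = welch, n = n),
            class = "feature_stats")
}

#' @export
print.feature_stats <- function(x, ...) {
  cat(sprintf("<feature_stats> n = %d\n", x$n))
  print(round(x$correlation, 3))
  invisible(x)
}

# ---- Grad-CAM ---------------------------------------------------------------

# pool gradients per channel, weight activations, rectify, upsample, scale
gradcam_core <- function(activation, gradient, out_hw) {
  stopifnot(length(dim(activation)) == 3,
            all(dim(activation) == dim(gradient)))
  w <- apply(gradient, 3, mean)
  map <- matrix(0, dim(activation)[1], dim(activation)[2])
  for (c in seq_along(w)) map <- map + w[c] * activation[, , c]
  map <- pmax(map, 0)
  map <- upsample_bilinear(map, out_hw[1], out_hw[2])
  rng <- range(map)
  if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
}

upsample_bilinear <- function(m, h, w) {
  if (nrow(m) == 1) m <- m[c(1, 1), , drop = FALSE]
  if (ncol(m) == 1) m <- m[, c(1, 1), drop = FALSE]
  src_y <- seq(0.5, nrow(m) - 0.5) / nrow(m)
  src_x <- seq(0.5, ncol(m) - 0.5) / ncol(m)
  out_y <- seq(0.5, h - 0.5) / h
  out_x <- seq(0.5, w - 0.5) / w
  # interpolate rows then columns, holding endpoints
  tmp <- apply(m, 2, function(col) {
    approx(src_y, col, xout = out_y, rule = 2)$y
  })
  t(apply(tmp, 1, function(row) {
    approx(src_x, row, xout = out_x, rule = 2)$y
  }))
}

#' Gradient-weighted class activation map
#'
#' Grad-CAM for the fusion model or the image-only classifier: the gradient
#' of the target-class score (pre-softmax logit) with respect to the chosen
#' convolutional stage's activation maps is global-average-pooled into
#' per-channel weights; the rectified weighted sum of activations is
#' upsampled to the image size and min-max scaled to \[0, 1\]. The
#' `"last"` stage (stage 4) has coarser native resolution than the
#' `"penultimate"` stage (stage 3).
#'
#' @param fit A `miml_fit` or `image_classifier_fit`.
#' @param image One crop (matrix or H x W x C array).
#' @param features The cell's feature vector (fusion model only), already
#'   normalized; a row of a normalized feature table or a numeric vector.
#' @param target_class Class label or index to explain (default: predicted).
#' @param layer `"penultimate"` or `"last"`.
#' @return A `grad_cam_map`: the heat map matrix (image size, values in
#'   \[0, 1\]) with the input image and class attached as attributes.
#' @export
grad_cam <- function(fit, image, features = NULL, target_class = NULL,
                     layer = c("last", "penultimate")) {
  layer <- match.arg(layer, c("last", "penultimate"))
  stage <- if (layer == "last") 4L else 3L
  if (inherits(fit, "miml_fit")) {
    model <- fit$model
    if (is.null(features)) abort("the fusion model needs the feature vector")
    if (is.data.frame(features)) features <- as.numeric(features[1, model$cfg$features])
    x <- as_image_batch(image, model$cfg$encoder)
    fw <- miml_fw(model, x, matrix(features, ncol = 1), training = FALSE,
                  keep_cache = TRUE)
    k <- resolve_class(target_class, fw$probs, fit$levels)
    dlogits <- matrix(0, nrow(fw$logits), 1)
    dlogits[k, 1] <- 1
    bw <- miml_bw(fw$model, fw$cache, dlogits, stop_at_stage = stage)
    act <- fw$stage_acts[[stage]][, , , 1, drop = FALSE]
    grad <- bw$d_stage[, , , 1, drop = FALSE]
  } else if (inherits(fit, "image_classifier_fit")) {
    cfg <- fit$model$cfg
    x <- as_image_batch(image, cfg)
    fw <- encoder_fw(fit$model, x, training = FALSE, with_head = TRUE)
    probs <- softmax_cols(fw$logits)
    k <- resolve_class(target_class, probs, fit$levels)
    dlogits <- matrix(0, nrow(fw$logits), 1)
    dlogits[k, 1] <- 1
    bw <- encoder_bw(fw$enc, fw$cache, dlogits = dlogits,
                     stop_at_stage = stage)
    act <- fw$stage_acts[[stage]][, , , 1, drop = FALSE]
    grad <- bw$d_stage[, , , 1, drop = FALSE]
  } else {
    abort("`fit` must be a miml_fit or image_classifier_fit")
  }
  dims <- dim(act)
  dim(act) <- dims[1:3]
  dim(grad) <- dims[1:3]
  img_hw <- dim(x)[1:2]
  map <- gradcam_core(act, grad, img_hw)
  structure(map, class = "grad_cam_map",
            image = if (is.matrix(image)) image else x[, , 1, 1] * 255,
            target_class = k, layer = layer)
}

resolve_class <- function(target_class, probs, levels) {
  if (is.null(target_class)) return(which.max(probs[, 1]))
  if (is.character(target_class)) {
    k <- match(target_class, levels)
    if (is.na(k)) abort(sprintf("unknown class '%s'", target_class))
    return(k)
  }
  as.integer(target_class)
}

# ---- t-SNE and patch inspection ---------------------------------------------

#' t-SNE embedding of the latent space
#'
#' Seeded two-dimensional t-SNE (via Rtsne) of model embeddings, with a
#' cluster-overlap score: the fraction of points whose nearest neighbor in
#' the 2-D embedding carries a different label (0 = perfectly separated).
#'
#' @param embeddings Numeric matrix, one row per example (e.g. from
#'   [miml_latent()]).
#' @param labels Class labels aligned to rows.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; requires `nrow >= 3 * perplexity + 2`.
#' @return A `tsne_embedding` tibble (`x`, `y`, `label`) with the overlap
#'   score as attribute `overlap`.
#' @export
latent_tsne <- function(embeddings, labels, seed = 42L, perplexity = 30) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 3 * perplexity + 2) {
    abort(sprintf("too few points (%d) for perplexity %g", n, perplexity))
  }
  coords <- with_seed(seed, {
    Rtsne::Rtsne(embeddings, dims = 2, perplexity = perplexity,
                 check_duplicates = FALSE, pca = TRUE, verbose = FALSE)$Y
  })
  d2 <- as.matrix(stats::dist(coords))^2
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  overlap <- mean(as.character(labels) != as.character(labels)[nn])
  out <- tibble(x = coords[, 1], y = coords[, 2], label = labels)
  attr(out, "overlap") <- overlap
  class(out) <- c("tsne_embedding", class(out))
  out
}

#' Sample image groups from latent-space patches
#'
#' Randomly selects `k_patches` patch centers among the embedded points
#' (seeded) and collects the images whose embeddings fall within
#' `patch_radius` of each center, for visual inspection of what nearby
#' latent positions look like.
#'
#' @param coords A `tsne_embedding` (or 2-column matrix).
#' @param images List of images aligned to the embedding rows.
#' @param k_patches Number of patches.
#' @param patch_radius Patch radius in embedding units (default: 10% of the
#'   larger coordinate range).
#' @param seed Integer seed.
#' @return List of patches, each with `center`, `members` (row indices) and
#'   `images`. Empty patches are dropped with a warning.
#' @export
patch_gallery <- function(coords, images, k_patches = 3, patch_radius = NULL,
                          seed = 1L) {
  xy <- if (inherits(coords, "tsne_embedding")) {
    cbind(coords$x, coords$y)
  } else {
    as.matrix(coords)
  }
  if (nrow(xy) != length(images)) abort("coords and images must align")
  if (is.null(patch_radius)) {
    patch_radius <- 0.1 * max(diff(range(xy[, 1])), diff(range(xy[, 2])))
  }
  centers <- with_seed(seed, sample.int(nrow(xy), k_patches))
  out <- lapply(centers, function(ci) {
    d <- sqrt((xy[, 1] - xy[ci, 1])^2 + (xy[, 2] - xy[ci, 2])^2)
    members <- which(d <= patch_radius)
    list(center = xy[ci, ], members = members, images = images[members])
  })
  keep <- vapply(out, function(p) length(p$members) > 0, TRUE)
  if (!all(keep)) warn("dropping empty latent-space patches")
  out[keep]
}
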