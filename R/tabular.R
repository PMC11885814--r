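# Classical classifiers on the mechanical-feature table. No classification
# package beyond stats is available in the target environment, so the SVM
# (kernelized Pegasos), CART tree, bagged forest and KNN are implemented
# here with conventional defaults; logistic regression goes through glm.

#' Fit one tabular classifier
#'
#' @param data Tibble holding the feature columns and a `label` column
#'   (features are expected on a common 0-1 scale; see [fit_normalizer()]).
#' @param kind One of `"lr"`, `"svm"`, `"dt"`, `"rf"`, `"knn"`, `"nn"`.
#' @param features Feature columns to train on.
#' @param seed Integer seed (stochastic models).
#' @param k Neighbors for KNN (ties broken by smallest class index).
#' @param n_trees Trees in the forest.
#' @param max_depth Maximum tree depth (`Inf` = grow to purity).
#' @param min_split Minimum node size to attempt a split.
#' @param gamma RBF kernel width for the SVM (default `1/d`).
#' @param lambda Pegasos regularization (default `1/n`).
#' @param svm_iters Pegasos iterations (default `20 * n`).
#' @param nn_epochs Epochs for the feature-network model kind.
#' @return A `tabular_model`.
#' @export
fit_tabular_model <- function(data, kind = c("lr", "svm", "dt", "rf", "knn", "nn"),
                              features, seed = 1L, k = 5L, n_trees = 100L,
                              max_depth = Inf, min_split = 2L, gamma = NULL,
                              lambda = NULL, svm_iters = NULL,
                              nn_epochs = 100L) {
  kind <- match.arg(kind)
  y <- droplevels(factor(data$label))
  if (nlevels(y) < 2) abort("training data must contain at least 2 classes")
  x <- as.matrix(data[features])
  storage.mode(x) <- "double"
  fitted <- with_seed(seed, switch(
    kind,
    lr = {
      if (nlevels(y) != 2) abort("logistic regression supports 2 classes")
      df <- as.data.frame(x)
      df$.y <- as.integer(y) - 1L
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    knn = list(x = x, y = as.integer(y), k = as.integer(k)),
    dt = grow_tree(x, as.integer(y), nlevels(y), max_depth, min_split,
                   mtry = ncol(x)),
    rf = {
      mtry <- max(1L, floor(sqrt(ncol(x))))
      lapply(seq_len(n_trees), function(i) {
        boot <- sample(nrow(x), replace = TRUE)
        grow_tree(x[boot, , drop = FALSE], as.integer(y)[boot], nlevels(y),
                  max_depth, min_split, mtry = mtry)
      })
    },
    svm = {
      if (nlevels(y) != 2) abort("the SVM supports 2 classes")
      fit_pegasos(x, ifelse(as.integer(y) == 1, -1, 1),
                  gamma %||% 1 / ncol(x), lambda %||% 1 / nrow(x),
                  svm_iters %||% max(2000L, 20L * nrow(x)))
    },
    nn = {
      cfg <- feature_nn_config(input_dim = length(features),
                               n_classes = nlevels(y))
      dtr <- data
      dtr$label <- y
      # hold out a slice of the training data for early stopping
      idx <- sample(nrow(dtr))
      n_val <- max(2L, floor(0.1 * nrow(dtr)))
      train_feature_nn(dtr[idx[-seq_len(n_val)], ], features = features,
                       config = cfg, epochs = nn_epochs,
                       seed = derive_seed(seed, 5),
                       val = dtr[idx[seq_len(n_val)], ])
    }))
  structure(list(kind = kind, fit = fitted, features = features,
                 levels = levels(y), seed = seed),
            class = "tabular_model")
}

#' @export
print.tabular_model <- function(x, ...) {
  cat(sprintf("<tabular_model> %s on (%s); classes: %s\n", toupper(x$kind),
              paste(x$features, collapse = ", "),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
predict.tabular_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$features])
  storage.mode(x) <- "double"
  idx <- switch(
    object$kind,
    lr = {
      p <- predict(object$fit, newdata = as.data.frame(x), type = "response")
      ifelse(p > 0.5, 2L, 1L)
    },
    knn = knn_predict(object$fit, x),
    dt = tree_predict(object$fit, x),
    rf = {
      votes <- vapply(object$fit, tree_predict, integer(nrow(x)), x = x)
      if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(x))
      apply(votes, 1, function(v) {
        tab <- tabulate(v, length(object$levels))
        which.max(tab)  # ties -> smallest class index
      })
    },
    svm = ifelse(pegasos_decision(object$fit, x) >= 0, 2L, 1L),
    nn = as.integer(predict(object$fit, as_tibble(as.data.frame(x)),
                            type = "class")))
  factor(object$levels[idx], levels = object$levels)
}

# ---- KNN --------------------------------------------------------------------

knn_predict <- function(fit, xnew) {
  d2 <- outer(rowSums(xnew^2), rowSums(fit$x^2), `+`) -
    2 * xnew %*% t(fit$x)
  apply(d2, 1, function(di) {
    nb <- fit$y[order(di)[seq_len(min(fit$k, length(di)))]]
    tab <- tabulate(nb, max(fit$y))
    which.max(tab)  # ties -> smallest class index
  })
}

# ---- CART -------------------------------------------------------------------

# Recursive CART with Gini impurity; mtry features considered per split.
grow_tree <- function(x, y, n_classes, max_depth = Inf, min_split = 2L,
                      mtry = ncol(x), depth = 0L) {
  counts <- tabulate(y, n_classes)
  node_class <- which.max(counts)
  if (length(unique(y)) == 1L || nrow(x) < min_split || depth >= max_depth) {
    return(list(leaf = TRUE, class = node_class))
  }
  feats <- if (mtry < ncol(x)) sample.int(ncol(x), mtry) else seq_len(ncol(x))
  best <- list(gain = -Inf)
  n <- length(y)
  parent_gini <- 1 - sum((counts / n)^2)
  for (j in feats) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    ys <- y[ord]
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    # cumulative class counts at each candidate split point
    cum <- vapply(seq_len(n_classes), function(k) cumsum(ys == k), numeric(n))
    nl <- distinct
    cl <- cum[distinct, , drop = FALSE]
    cr <- matrix(counts, nrow = length(distinct), ncol = n_classes,
                 byrow = TRUE) - cl
    gl <- 1 - rowSums((cl / nl)^2)
    gr <- 1 - rowSums((cr / (n - nl))^2)
    gain <- parent_gini - (nl * gl + (n - nl) * gr) / n
    b <- which.max(gain)
    if (gain[b] > best$gain + 1e-12) {
      best <- list(gain = gain[b], feature = j,
                   threshold = (xs[distinct[b]] + xs[distinct[b] + 1]) / 2)
    }
  }
  if (!is.finite(best$gain) || best$gain <= 1e-12) {
    return(list(leaf = TRUE, class = node_class))
  }
  left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       class = node_class,
       left = grow_tree(x[left, , drop = FALSE], y[left], n_classes,
                        max_depth, min_split, mtry, depth + 1L),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], n_classes,
                         max_depth, min_split, mtry, depth + 1L))
}

tree_predict <- function(tree, x) {
  out <- integer(nrow(x))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- node$class
      return()
    }
    left <- x[idx, node$feature] <= node$threshold
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree, seq_len(nrow(x)))
  out
}

# ---- kernel SVM (Pegasos) ---------------------------------------------------

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

fit_pegasos <- function(x, y, gamma, lambda, iters) {
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n)
  for (t in seq_len(iters)) {
    i <- sample.int(n, 1L)
    f <- sum(alpha * y * K[, i]) / (lambda * t)
    if (y[i] * f < 1) alpha[i] <- alpha[i] + 1
  }
  list(x = x, y = y, alpha = alpha, gamma = gamma,
       scale = 1 / (lambda * iters))
}

pegasos_decision <- function(fit, xnew) {
  K <- rbf_kernel(xnew, fit$x, fit$gamma)
  as.numeric(K %*% (fit$alpha * fit$y)) * fit$scale
}

# ---- cross-validation -------------------------------------------------------

#' Five-fold cross-validation of a tabular classifier
#'
#' Trains on four folds and validates on the held-out fold, cycling all
#' folds. Folds come from the dataset's `fold` column (test-split rows,
#' which carry no fold, are ignored).
#'
#' @param data Feature table with `label`, `fold` and the feature columns,
#'   normalized to a common scale.
#' @param kind Model kind, as in [fit_tabular_model()].
#' @param features Feature columns.
#' @param seed Integer seed; per-fold seeds are derived from it, so results
#'   are reproducible.
#' @param ... Passed to [fit_tabular_model()].
#' @return A `cv_results` object: per-fold tibble plus mean/sd accuracy
#'   (see [tidy()] / [glance()] methods).
#' @export
cross_validate <- function(data, kind, features = c("DI", "TT", "vmax"),
                           seed = 1L, ...) {
  data <- dplyr::filter(data, !is.na(.data$fold))
  folds <- sort(unique(data$fold))
  if (length(folds) < 2) abort("need at least 2 folds")
  per_fold <- purrr::map(folds, function(f) {
    tr <- dplyr::filter(data, .data$fold != f)
    va <- dplyr::filter(data, .data$fold == f)
    if (nlevels(droplevels(factor(tr$label))) < 2) {
      abort(sprintf("training folds for fold %d contain a single class", f))
    }
    fit <- fit_tabular_model(tr, kind, features,
                             seed = derive_seed(seed, f), ...)
    pred <- predict(fit, va)
    tibble(fold = f, n = nrow(va),
           accuracy = mean(as.character(pred) == as.character(va$label)))
  })
  res <- dplyr::bind_rows(per_fold)
  structure(list(kind = kind, features = features, per_fold = res,
                 mean = mean(res$accuracy), sd = sd(res$accuracy),
                 seed = seed),
            class = "cv_results")
}

#' @export
print.cv_results <- function(x, ...) {
  cat(sprintf("<cv_results> %s: accuracy %.3f +/- %.3f over %d folds\n",
              toupper(x$kind), x$mean, x$sd, nrow(x$per_fold)))
  invisible(x)
}

#' Decision surface of a two-feature model
#'
#' Evaluates a trained [fit_tabular_model()] on a regular grid over the unit
#' square of its two features, for plotting the pairwise decision regions.
#'
#' @param model A `tabular_model` trained on exactly two features.
#' @param grid_resolution Points per axis.
#' @return A `decision_surface` tibble with the two feature coordinates and
#'   the predicted `label` per grid point.
#' @export
decision_surface <- function(model, grid_resolution = 100) {
  if (!inherits(model, "tabular_model")) abort("`model` must be a fitted tabular_model")
  if (length(model$features) != 2) {
    abort("decision surfaces require a model trained on exactly two features")
  }
  s <- seq(0, 1, length.out = grid_resolution)
  grid <- tidyr::expand_grid(.x = s, .y = s)
  names(grid) <- model$features
  grid$label <- predict(model, grid)
  attr(grid, "kind") <- model$kind
  class(grid) <- c("decision_surface", class(grid))
  grid
}
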