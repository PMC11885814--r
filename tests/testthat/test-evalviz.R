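test_that("confusion-count metrics match direct substitution", {
  m <- compute_metrics(c(TP = 9, TN = 9, FP = 1, FN = 1))
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)

  m2 <- compute_metrics(c(TP = 50, FP = 5, FN = 5, TN = 40))
  expect_equal(m2$f1, 100 / 110)

  m3 <- compute_metrics(c(TP = 7, TN = 13, FP = 0, FN = 0))
  expect_equal(unlist(m3[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  expect_error(compute_metrics(c(TP = -1, TN = 1, FP = 1, FN = 1)),
               "non-negative")
  expect_warning(m4 <- compute_metrics(c(TP = 0, TN = 5, FP = 0, FN = 0)),
                 "undefined")
  expect_true(is.nan(m4$precision))
})

test_that("F1 equals the harmonic mean of precision and recall", {
  set.seed(4)
  for (i in 1:25) {
    cts <- c(TP = rpois(1, 20) + 1, TN = rpois(1, 20),
             FP = rpois(1, 5) + 1, FN = rpois(1, 5) + 1)
    m <- compute_metrics(cts)
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall), tolerance = 1e-12)
  }
})

test_that("ROC/AUC handles separation, ties, and matches the rank formula", {
  r1 <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c("pos", "pos", "neg", "neg"),
                positive = "pos")
  expect_equal(r1$auc[1], 1)

  r2 <- roc_auc(rep(0.5, 10), rep(c("a", "b"), 5), positive = "b")
  expect_equal(r2$auc[1], 0.5)

  # curve contract: starts (0,0), ends (1,1), both coordinates non-decreasing
  set.seed(11)
  scores <- round(runif(200), 2)   # heavy ties
  labels <- ifelse(runif(200) < plogis(4 * scores - 2), "b", "a")
  if (length(unique(labels)) < 2) labels[1:2] <- c("a", "b")
  roc <- roc_auc(scores, labels, positive = "b")
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))

  # independent oracle: AUC = P(score_pos > score_neg) + 0.5 P(tie)
  pos <- scores[labels == "b"]; neg <- scores[labels == "a"]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(roc$auc[1], mean(cmp), tolerance = 1e-12)

  # invariance under a strictly monotone transform
  roc2 <- roc_auc(exp(3 * scores), labels, positive = "b")
  expect_equal(roc2$auc[1], roc$auc[1], tolerance = 1e-12)

  expect_error(roc_auc(runif(5), rep("a", 5)), "both classes")
})

test_that("random scores give chance-level AUC", {
  mimlr:::with_seed(12, {
    scores <- runif(2000)
    labels <- rep(c("a", "b"), 1000)
    expect_lt(abs(roc_auc(scores, labels, positive = "b")$auc[1] - 0.5), 0.03)
  })
})

test_that("feature statistics: perfect linearity, symmetry, and errors", {
  tbl <- tibble::tibble(DI = seq(0.1, 1, length.out = 10))
  tbl$TT <- 2 * tbl$DI
  tbl$vmax <- mimlr:::with_seed(1, runif(10))
  fs <- feature_statistics(tbl, features = c("DI", "TT", "vmax"))
  pair <- fs$pairs[fs$pairs$feature_x == "DI" & fs$pairs$feature_y == "TT", ]
  expect_equal(pair$r, 1, tolerance = 1e-12)
  expect_equal(pair$slope, 1, tolerance = 1e-12)   # standardized slope = |r|
  # symmetric correlation matrix with unit diagonal
  expect_equal(fs$correlation, t(fs$correlation))
  expect_equal(unname(diag(fs$correlation)), rep(1, 3))
  # raw slope mode recovers the factor of 2
  fs_raw <- feature_statistics(tbl, features = c("DI", "TT"), raw_slope = TRUE)
  expect_equal(fs_raw$pairs$slope[1], 2, tolerance = 1e-12)

  expect_error(feature_statistics(tibble::tibble(DI = rep(1, 5), TT = 1:5)),
               "constant feature column")
  expect_error(feature_statistics(tbl[1:2, ]), "at least 3")
})

test_that("Pearson p-values agree with a permutation null", {
  # moderate correlation at n = 12; the permutation p (1e5 draws) should
  # agree with the exact-t p up to Monte-Carlo and approximation error
  mimlr:::with_seed(5, {
    x <- rnorm(12)
    y <- 0.55 * x + rnorm(12)
    fs <- feature_statistics(tibble::tibble(DI = plogis(x), TT = y),
                             features = c("DI", "TT"))
    r_obs <- fs$pairs$r[1]
    perm <- replicate(1e5, abs(cor(plogis(x), sample(y))))
    p_perm <- mean(perm >= abs(r_obs))
    expect_lt(abs(fs$pairs$p[1] - p_perm), 0.015)
  })
})

test_that("Welch t-test separates class-conditional DI", {
  tbl <- mimlr:::with_seed(6, tibble::tibble(
    DI = c(rnorm(300, 0.66, 0.09), rnorm(300, 0.722, 0.085)),
    TT = runif(600), vmax = runif(600),
    label = rep(c("WBC", "HCT116"), each = 300)))
  fs <- feature_statistics(tbl)
  expect_lt(fs$welch_di$p.value, 1e-3)
  expect_equal(nrow(fs$class_stats), 3 * 2)
})

test_that("Grad-CAM core equals a hand-computed one-filter chain rule", {
  # one 3x3 filter, ReLU, global average pool, linear head: the map is the
  # rectified product of the pooled gradient weight and the activation
  set.seed(13)
  x <- array(runif(8 * 8 * 1), c(8, 8, 1, 1))
  conv <- mimlr:::nn_conv(1L, 1L, 3L)
  conv$w[] <- rep(c(0.3, -0.15), length.out = 9)   # hand-set filter
  conv$b[] <- 0.02
  wlin <- matrix(c(1.3, -0.7), 2, 1)

  cf <- mimlr:::conv_fw_layer(conv, x)
  rf <- mimlr:::relu_fw(cf$y)
  gp <- mimlr:::gap_fw(rf$y)
  # target class 1 score = wlin[1,] %*% z; chain rule by hand:
  dz <- matrix(wlin[1, ], 1, 1)
  dA_hand <- array(wlin[1, 1] / 64, c(8, 8, 1, 1)) * (cf$y > 0)

  # the same gradient through the package's backward functions
  dgap <- mimlr:::gap_bw(gp$cache, dz)
  dA_pkg <- mimlr:::relu_bw(rf$cache, dgap)
  expect_equal(dA_pkg, dA_hand, tolerance = 1e-12)

  A <- array(rf$y, c(8, 8, 1))
  G <- array(dA_pkg, c(8, 8, 1))
  map <- mimlr:::gradcam_core(A, G, c(8, 8))
  w_hand <- mean(G)
  hand <- pmax(w_hand * A[, , 1], 0)
  rng <- range(hand)
  hand <- (hand - rng[1]) / diff(rng)
  expect_equal(map, hand, tolerance = 1e-12)
  expect_true(all(map >= 0 & map <= 1))
})

test_that("grad_cam maps align to the image and coarsen with depth", {
  ds <- small_dataset()
  fit <- train_miml(ds, small_miml_config(), epochs = 1, seed = 3)
  feats <- apply_normalizer(ds[1, ], fit$normalizer)[, c("DI", "TT", "vmax")]
  for (layer in c("penultimate", "last")) {
    map <- grad_cam(fit, ds$image_exit[[1]], features = feats, layer = layer)
    expect_equal(dim(unclass(map)), c(32, 32))
    expect_true(all(map >= 0 & map <= 1))
  }
  # native resolution: last stage is coarser than the penultimate stage
  x <- mimlr:::as_image_batch(ds$image_exit[[1]], fit$model$cfg$encoder)
  fw <- mimlr:::encoder_fw(fit$model$encoder, x, FALSE, FALSE)
  expect_lt(dim(fw$stage_acts[[4]])[1], dim(fw$stage_acts[[3]])[1])
  expect_error(grad_cam(fit, ds$image_exit[[1]], features = feats,
                        layer = "stem"), "arg")
})

test_that("latent t-SNE separates well-separated blobs and is seeded", {
  mimlr:::with_seed(21, {
    emb <- rbind(matrix(rnorm(60 * 64, 0), 60),
                 matrix(rnorm(60 * 64, 8), 60))
    labels <- rep(c("a", "b"), each = 60)
    t1 <- latent_tsne(emb, labels, seed = 2, perplexity = 10)
    expect_equal(dim(t1), c(120, 3))
    expect_lt(attr(t1, "overlap"), 0.05)
    t2 <- latent_tsne(emb, labels, seed = 2, perplexity = 10)
    expect_identical(t1$x, t2$x)
    expect_error(latent_tsne(emb[1:20, ], labels[1:20], perplexity = 10),
                 "too few")
  })
})

test_that("patch galleries sample latent neighborhoods reproducibly", {
  mimlr:::with_seed(22, {
    coords <- matrix(runif(200), 100, 2)
    images <- as.list(seq_len(100))
    g <- patch_gallery(coords, images, k_patches = 3, patch_radius = 0.2,
                       seed = 5)
    expect_length(g, 3)
    expect_true(all(vapply(g, function(p) length(p$members) > 0, TRUE)))
    # radius covering everything puts every image in one patch
    g_all <- patch_gallery(coords, images, k_patches = 1, patch_radius = 10,
                           seed = 5)
    expect_length(g_all[[1]]$members, 100)
    g2 <- patch_gallery(coords, images, k_patches = 3, patch_radius = 0.2,
                        seed = 5)
    expect_identical(lapply(g, `[[`, "members"), lapply(g2, `[[`, "members"))
  })
})
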