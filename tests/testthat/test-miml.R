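# Fusion-model behaviors on a desk-scale encoder (32 px crops, 8 base
# filters); the reference-width contracts live in test-encoder.R.

test_that("records missing a modality are rejected with their ids", {
  ds <- small_dataset()
  ds$image_exit[3] <- list(NULL)
  expect_error(mimlr:::dataset_examples(ds, c("DI", "TT", "vmax")),
               "missing a modality.*cell_00003")
  ds2 <- small_dataset()
  ds2$DI[5] <- NA
  expect_error(mimlr:::dataset_examples(ds2, c("DI", "TT", "vmax")),
               "cell_00005")
})

test_that("untrained model predicts near-uniformly: initial loss <= ln(K) + 0.1", {
  ds <- small_dataset()
  model <- build_miml(small_miml_config(), seed = 1)
  # first training batch: batch-norm uses batch statistics
  x <- mimlr:::batch_images(ds$image_exit[1:20], model$cfg$encoder)
  m <- matrix(runif(3 * 20), 3, 20)
  fw <- mimlr:::miml_fw(model, x, m, training = TRUE)
  y <- as.integer(ds$label[1:20])
  expect_lte(mimlr:::cross_entropy(fw$probs, y), log(2) + 0.1)
  probs <- forward_miml(model, ds$image_exit[1:20], m)
  expect_equal(colSums(probs), rep(1, 20), tolerance = 1e-6)
  # eval-mode determinism
  probs2 <- forward_miml(model, ds$image_exit[1:20],
                         data.frame(DI = ds$DI[1:20], TT = runif(20),
                                    vmax = runif(20))[, 1:3] * 0 + 0.5)
  probs3 <- forward_miml(model, ds$image_exit[1:20],
                         matrix(0.5, 3, 20))
  expect_identical(probs2, probs3)
})

test_that("one training step sends gradient into every part of both branches", {
  ds <- small_dataset()
  model <- build_miml(small_miml_config(), seed = 2)
  x <- mimlr:::batch_images(ds$image_exit[1:8], model$cfg$encoder)
  m <- matrix(runif(3 * 8), 3, 8)
  fw <- mimlr:::miml_fw(model, x, m, training = TRUE, keep_cache = TRUE)
  bw <- mimlr:::miml_bw(fw$model, fw$cache,
                        mimlr:::ce_grad(fw$probs, rep(1:2, 4)))
  flat <- mimlr:::flatten_params(unclass(model))
  for (nm in names(flat)) {
    # correctly gradient-free tensors: convolution biases feed straight
    # into batch norm (mean removal), and the encoder's classification
    # head plus the feature net's logit layer are bypassed under latent
    # fusion
    if (grepl("conv.*\\.b$|stem\\.conv\\.b$", nm)) next
    if (grepl("^encoder\\.fc\\.|^feature_nn\\.l3\\.", nm)) next
    expect_true(any(abs(as.numeric(bw$grads[[nm]])) > 0), label = nm)
  }
  # both modality branches received gradient
  expect_true(any(grepl("^encoder\\.stages", names(bw$grads))))
  expect_true(any(grepl("^feature_nn\\.", names(bw$grads))))
})

test_that("checkpoints serialize, reload, and resume exactly", {
  ds <- small_dataset()
  cfg <- small_miml_config()
  full <- train_miml(ds, cfg, epochs = 2, seed = 5, keep = "last")
  part <- train_miml(ds, cfg, epochs = 1, seed = 5, keep = "last")

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(part, path)
  part2 <- load_checkpoint(path)
  resumed <- train_miml(ds, epochs = 1, resume = part2, keep = "last")
  expect_equal(resumed$history, full$history, tolerance = 1e-12)
  p1 <- predict(full, ds[1:5, ])
  p2 <- predict(resumed, ds[1:5, ])
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("shuffling the image-feature pairing degrades validation accuracy", {
  ds <- make_dataset(complementarity_config(n_per_class = c(A = 150, B = 150),
                                            seed = 31))
  cfg <- small_miml_config()
  fit <- train_miml(ds, cfg, epochs = 6, seed = 9)
  # break the pairing: permute the feature columns across cells, keeping
  # labels with the images, so features carry no class information
  ds_shuf <- ds
  perm <- mimlr:::with_seed(10, sample(nrow(ds)))
  for (f in c("DI", "TT", "vmax", "DIR")) ds_shuf[[f]] <- ds[[f]][perm]
  fit_shuf <- train_miml(ds_shuf, cfg, epochs = 6, seed = 9)
  expect_gt(max(fit$history$val_acc), max(fit_shuf$history$val_acc))
})

test_that("with the image branch zeroed and frozen, the fusion model matches
           the feature-only network", {
  ds <- make_dataset(complementarity_config(n_per_class = c(A = 300, B = 300),
                                            seed = 42))
  cfg <- small_miml_config()
  model <- build_miml(cfg, seed = 7)
  flat <- mimlr:::flatten_params(unclass(model))
  for (nm in grep("^encoder\\.", names(flat), value = TRUE)) {
    flat[[nm]] <- flat[[nm]] * 0
  }
  model <- mimlr:::assign_params(model, flat)
  warm <- structure(
    list(model = model,
         normalizer = fit_normalizer(dplyr::filter(ds, split == "train"),
                                     c("TT", "vmax")),
         levels = levels(droplevels(ds$label)),
         history = tibble::tibble(epoch = 0L, train_loss = NA_real_,
                                  train_acc = NA_real_, val_loss = NA_real_,
                                  val_acc = NA_real_),
         seed = 7, opt = mimlr:::adam_init(flat),
         rng_state = mimlr:::with_seed(7, get(".Random.seed", envir = globalenv()))),
    class = "miml_fit")
  zeroed <- train_miml(ds, epochs = 10, seed = 1, resume = warm,
                       encoder_lr_scale = 0)
  featnn <- train_feature_nn(ds, epochs = 100, seed = 1)
  acc_zeroed <- max(zeroed$history$val_acc, na.rm = TRUE)
  acc_feat <- max(featnn$history$val_acc)
  expect_lt(abs(acc_zeroed - acc_feat), 0.025)
  # the frozen encoder stayed zero
  flat_after <- mimlr:::flatten_params(unclass(zeroed$model))
  expect_true(all(vapply(grep("^encoder\\..*\\.w$", names(flat_after),
                              value = TRUE),
                         function(nm) all(flat_after[[nm]] == 0), TRUE)))
})

test_that("transfer learning re-uses weights and adapts to a stiffened variant", {
  ecfg <- small_encoder_config()
  mcfg <- small_miml_config()
  src <- make_dataset(generator_config(
    n_per_class = c(WBC = 150, HCT116 = 150), crop_size = 32, seed = 42))
  src_fit <- train_miml(src, mcfg, epochs = 6, seed = 42)

  # class-count surgery: 2 -> 3 classes re-initializes only the final layer
  three <- make_dataset(generator_config(
    class_profiles = list(wbc_profile(), hct116_profile(),
                          hct_stiffened_profile()),
    n_per_class = c(WBC = 20, HCT116 = 20, `HCT-Stiffened` = 20),
    crop_size = 32, seed = 3))
  tf3 <- miml_transfer(src_fit, three, epochs = 1, seed = 1)
  expect_equal(dim(tf3$model$head$l3$w), c(3, 32))
  expect_equal(dim(tf3$model$head$l2$w), dim(src_fit$model$head$l2$w))
  expect_equal(tf3$model$encoder$cfg$base_filters, ecfg$base_filters)

  # fine-tuning on the chemically stiffened variant: 51 train cells = 102
  # training examples, the 30-epoch schedule
  nds <- make_dataset(generator_config(
    class_profiles = list(hct_stiffened_profile(), hct116_profile()),
    n_per_class = c(`HCT-Stiffened` = 102, HCT116 = 102),
    crop_size = 32, test_fraction = 0.5, n_folds = 2, seed = 7))
  expect_equal(2 * sum(nds$split == "train"), 102)
  te <- dplyr::filter(nds, split == "test")
  accs <- vapply(1:3, function(sd) {
    tf <- miml_transfer(src_fit, nds, epochs = 30, seed = sd)
    mean(as.character(predict(tf, te, type = "class")) ==
           as.character(te$label))
  }, 0)
  # images are identical across these classes by construction, so the
  # feature-only ceiling (~0.94) is not reachable end-to-end at 102
  # examples; fine-tuning still lands far above chance (~0.83 across
  # seeds). See the methods vignette for the full analysis.
  expect_gt(mean(accs), 0.75)

  # incompatible encoder config is rejected
  other <- train_miml(src, miml_config(encoder = encoder_config(
    input_size = c(48, 48), base_filters = 8)) , epochs = 1, seed = 1,
    ) |> try(silent = TRUE)
  expect_true(inherits(other, "try-error"))  # 48 px model cannot train on 32 px crops
})

test_that("tidy and glance summarize fitted models", {
  ds <- small_dataset()
  fit <- train_miml(ds, small_miml_config(), epochs = 2, seed = 1)
  h <- tidy(fit)
  expect_equal(nrow(h), 2)
  expect_named(h, c("epoch", "train_loss", "train_acc", "val_loss", "val_acc"))
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_gt(g$n_parameters, 1000)
  pr <- predict(fit, ds[1:6, ])
  expect_named(pr, c("cell_id", "label", "A", "B", ".pred"))
  expect_equal(rowSums(pr[, c("A", "B")]), rep(1, 6), tolerance = 1e-9)
})
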