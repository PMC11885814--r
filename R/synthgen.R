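#' Sample mechanical features for one synthetic cell class
#'
#' Draws `n` cells from the class-conditional distributions of a
#' [class_profile()]. DI comes from a normal truncated to \[0, 1\]; vmax from
#' a positive truncated normal; transition time follows the inverse law
#' `TT = c / vmax * (1 + eps)` with the noise level `eps` solved in closed
#' form from the sample moments so that the expected standardized regression
#' coefficient between vmax and TT equals the profile's `vtt_correlation`;
#' DIR is an independent positive normal. Values are raw (unnormalized).
#'
#' @param config A [generator_config()].
#' @param n Number of cells (0 gives an empty table with the feature columns).
#' @param class_name Name of a profile in `config`.
#' @param seed Integer seed (defaults to the config seed).
#'
#' @return A tibble with columns `DI`, `TT`, `vmax`, `DIR`.
#' @examples
#' sample_features(generator_config(), 5, "WBC", seed = 1)
#' @export
sample_features <- function(config, n, class_name, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    abort("`n` must be a non-negative integer")
  }
  prof <- config$class_profiles[[class_name]]
  if (is.null(prof)) {
    abort(sprintf("unknown class label '%s'; available: %s", class_name,
                  paste(names(config$class_profiles), collapse = ", ")))
  }
  if (n == 0) {
    return(tibble(DI = numeric(0), TT = numeric(0), vmax = numeric(0),
                  DIR = numeric(0)))
  }
  with_seed(seed, {
    di <- rtruncnorm(n, prof$di_mean, prof$di_sd, lower = 0, upper = 1)
    vmax <- rtruncnorm(n, prof$vmax_mean, prof$vmax_sd, lower = 0.05)
    base <- config$tt_scale / vmax
    sig <- tt_noise_sd(vmax, base, abs(prof$vtt_correlation))
    tt <- base * (1 + rnorm(n, 0, sig))
    tt <- pmax(tt, 0.05 * base)  # keep transition times positive
    dir <- rtruncnorm(n, prof$dir_mean, prof$dir_sd, lower = 1e-6)
    tibble(DI = di, TT = tt, vmax = vmax, DIR = dir)
  })
}

# Solve for the relative noise s.d. sigma such that, at the observed sample
# moments of vmax and base = c/vmax, cor(vmax, base * (1 + eps)) has
# magnitude r_target:  r^2 = cov(v,B)^2 / (var(v) * (var(B) + s^2 E[B^2])).
tt_noise_sd <- function(v, base, r_target) {
  if (length(v) < 3 || r_target <= 0) return(0)
  covvB <- cov(v, base)
  s2 <- (covvB^2 / (var(v) * r_target^2) - var(base)) / mean(base^2)
  sqrt(max(s2, 0))
}

# Area-conserving ellipse half-axes for a circle of radius r deformed to
# deformation index di: a*b = r^2 and (a-b)/(a+b) = di.
ellipse_axes <- function(r, di) {
  if (any(di < 0) || any(di >= 1)) abort("`di` must lie in [0, 1)")
  rho <- (1 + di) / (1 - di)
  list(a = r * sqrt(rho), b = r / sqrt(rho))
}

# Render one anti-aliased dark ellipse on a bright background.
# cx, cy in µm within the crop; returns an (H, W) intensity matrix (0-255).
draw_ellipse <- function(h_px, w_px, cx, cy, a, b, pixel_scale,
                         background, cell_intensity, edge_um = 0.5) {
  ys <- (seq_len(h_px) - 0.5) * pixel_scale
  xs <- (seq_len(w_px) - 0.5) * pixel_scale
  dy <- (ys - cy) / b
  dx <- (xs - cx) / a
  e <- sqrt(outer(dy^2, dx^2, `+`))
  # signed distance from the ellipse boundary, approximately in µm
  dist <- (e - 1) * sqrt(a * b)
  frac <- pmin(pmax(0.5 - dist / edge_um, 0), 1)
  background + (cell_intensity - background) * frac
}

render_cell_crop <- function(diameter, di, crop_size, pixel_scale,
                             background, cell_intensity, noise_sd,
                             gain = 1, shift = 0) {
  ax <- ellipse_axes(diameter / 2, di)
  ctr <- crop_size * pixel_scale / 2
  img <- draw_ellipse(crop_size, crop_size, ctr, ctr, ax$a, ax$b,
                      pixel_scale, background, cell_intensity)
  img <- img * gain + shift
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(crop_size^2, 0, noise_sd), crop_size)
  }
  pmin(pmax(img, 0), 255)
}

# gap profile g(x) of the channel (µm), cosine ramps of length `ramp` µm
gap_at <- function(x, geometry, ramp = 5) {
  pl <- constriction_planes(geometry)
  g <- rep(geometry$wide_gap, length(x))
  inside <- x >= pl["entry"] & x <= pl["exit"]
  g[inside] <- geometry$gap_height
  pre <- x > pl["entry"] - ramp & x < pl["entry"]
  g[pre] <- geometry$gap_height + (geometry$wide_gap - geometry$gap_height) *
    (1 + cos(pi * (x[pre] - (pl["entry"] - ramp)) / ramp)) / 2
  post <- x > pl["exit"] & x < pl["exit"] + ramp
  g[post] <- geometry$wide_gap - (geometry$wide_gap - geometry$gap_height) *
    (1 + cos(pi * (x[post] - pl["exit"]) / ramp)) / 2
  g
}

#' Render a full synthetic transit image sequence
#'
#' Produces timestamped grayscale frames of a single dark elliptical cell
#' translating left to right through the channel. Outside the constriction
#' the cell is a circle of the given diameter; inside, its minor axis is
#' compressed (area conserved) so that the mid-constriction shape has
#' deformation index `di_target`. The centroid speed follows mass
#' conservation (speed scales with the inverse local gap), so velocity peaks
#' inside the constriction.
#'
#' @param diameter Cell diameter, µm.
#' @param di_target Mid-constriction deformation index in \[0, 1).
#' @param geometry A [channel_geometry()].
#' @param n_frames Number of frames (at least 3).
#' @param noise_sd Additive Gaussian pixel noise (8-bit units).
#' @param seed Integer seed.
#' @param vmax_um_s Peak centroid speed inside the constriction, µm/s.
#' @param background,cell_intensity Intensities (8-bit units).
#'
#' @return A `frame_sequence`: list with `frames` (list of H x W matrices),
#'   `times` (s), `geometry`, and a `truth` tibble holding the per-frame
#'   ground-truth centroid (px), axes (px) and DI used for rendering.
#' @export
render_transit <- function(diameter, di_target, geometry = channel_geometry(),
                           n_frames = 25, noise_sd = 8, seed = 1L,
                           vmax_um_s = 4000, background = 200,
                           cell_intensity = 80) {
  check_number(diameter, "diameter", lower = 1e-6)
  if (n_frames < 3) abort("`n_frames` must be at least 3")
  if (di_target < 0 || di_target >= 1) {
    abort("`di_target` must lie in [0, 1); a value of 1 implies a minor axis of zero")
  }
  ellipse_axes(diameter / 2, di_target)  # validates the axes exist

  L <- geometry$channel_length
  x0 <- 0.1 * L
  x1 <- 0.9 * L
  # peak speed vmax_um_s occurs where the gap is narrowest
  v_of_x <- function(x) vmax_um_s * geometry$gap_height / gap_at(x, geometry)
  xs_fine <- seq(x0, x1, length.out = 2000)
  dt_fine <- diff(xs_fine) / v_of_x(xs_fine[-length(xs_fine)])
  t_fine <- c(0, cumsum(dt_fine))
  times <- seq(0, t_fine[length(t_fine)], length.out = n_frames)
  x_t <- approx(t_fine, xs_fine, xout = times)$y

  # compression fraction from the local gap; 1 mid-constriction, 0 outside
  s <- (geometry$wide_gap - gap_at(x_t, geometry)) /
    (geometry$wide_gap - geometry$gap_height)
  r <- diameter / 2
  b_mid <- ellipse_axes(r, di_target)$b
  b_t <- r - (r - b_mid) * s
  a_t <- r^2 / b_t
  di_t <- (a_t - b_t) / (a_t + b_t)

  h_px <- round(geometry$wide_gap / geometry$pixel_scale)
  w_px <- round(L / geometry$pixel_scale)
  cy <- geometry$wide_gap / 2
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(i) {
      img <- draw_ellipse(h_px, w_px, x_t[i], cy, a_t[i], b_t[i],
                          geometry$pixel_scale, background, cell_intensity)
      if (noise_sd > 0) {
        img <- img + matrix(rnorm(h_px * w_px, 0, noise_sd), h_px)
      }
      pmin(pmax(img, 0), 255)
    })
    structure(
      list(frames = frames, times = times, geometry = geometry,
           truth = tibble(
             time = times,
             x_px = x_t / geometry$pixel_scale,
             y_px = cy / geometry$pixel_scale,
             a_px = 2 * a_t / geometry$pixel_scale,
             b_px = 2 * b_t / geometry$pixel_scale,
             DI = di_t)),
      class = "frame_sequence"
    )
  })
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames of %d x %d px over %.4g s\n",
              length(x$frames), d[1], d[2], max(x$times)))
  invisible(x)
}

#' Generate the full synthetic benchmark dataset
#'
#' Samples per-cell mechanical features and diameters for every class,
#' renders the two images captured per cell (one at the beginning of the
#' squeeze — an undeformed circle — and one at its termination — the
#' deformed ellipse), and assigns splits and folds: a seeded shuffle holds
#' out `floor(test_fraction * N)` cells as the test split, and the remaining
#' train+val pool is dealt round-robin into `n_folds` folds (the last fold
#' is labelled `val`). Validation and test images receive a split-level
#' additive illumination shift plus per-image gain jitter, emulating
#' recordings taken on different days; training images keep the configured
#' baseline exactly.
#'
#' @param config A [generator_config()].
#' @return A `miml_dataset` tibble with one row per cell: `cell_id`,
#'   `label`, `split`, `fold`, `diameter`, `DI`, `TT`, `vmax`, `DIR`, and
#'   list-columns `image_entry`, `image_exit` of grayscale crop matrices.
#' @examples
#' cfg <- generator_config(n_per_class = c(WBC = 20, HCT116 = 20), crop_size = 32)
#' ds <- make_dataset(cfg)
#' dplyr::count(ds, label, split)
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  active <- names(config$n_per_class)[config$n_per_class > 0]
  if (length(active) < 2) {
    warn("single-class configuration: dataset is unusable for classification")
  }

  feats <- purrr::imap(config$n_per_class[config$n_per_class > 0],
                       function(n, cls) {
    prof <- config$class_profiles[[cls]]
    f <- sample_features(config, n, cls,
                         seed = derive_seed(config$seed, match(cls, names(config$class_profiles))))
    f$label <- cls
    f$diameter <- with_seed(
      derive_seed(config$seed, 100 + match(cls, names(config$class_profiles))),
      rtruncnorm(n, prof$diameter_mean, prof$diameter_sd, lower = 4))
    f
  })
  tbl <- dplyr::bind_rows(feats)
  n_total <- nrow(tbl)

  with_seed(derive_seed(config$seed, 999), {
    ord <- sample.int(n_total)
    tbl <- tbl[ord, ]
    n_test <- floor(config$test_fraction * n_total)
    split <- rep("train", n_total)
    fold <- rep(NA_integer_, n_total)
    if (n_test > 0) split[seq_len(n_test)] <- "test"
    pool <- which(split != "test")
    fold[pool] <- rep_len(seq_len(config$n_folds), length(pool))
    split[pool][fold[pool] == config$n_folds] <- "val"
    tbl$split <- split
    tbl$fold <- fold

    shift <- c(train = 0,
               val = runif(1, -config$illumination_shift_range,
                           config$illumination_shift_range),
               test = runif(1, -config$illumination_shift_range,
                            config$illumination_shift_range))

    cs <- config$crop_size
    render_row <- function(diameter, di, split) {
      g <- if (split == "train") 1 else rnorm(1, 1, 0.02)
      list(
        entry = render_cell_crop(diameter, 0, cs, config$geometry$pixel_scale,
                                 config$background, config$cell_intensity,
                                 config$noise_sd, gain = g,
                                 shift = shift[[split]]),
        exit = render_cell_crop(diameter, di, cs, config$geometry$pixel_scale,
                                config$background, config$cell_intensity,
                                config$noise_sd, gain = g,
                                shift = shift[[split]]))
    }
    imgs <- purrr::pmap(list(tbl$diameter, tbl$DI, tbl$split), render_row)

    out <- tibble(
      cell_id = sprintf("cell_%05d", seq_len(n_total)),
      label = factor(tbl$label, levels = names(config$class_profiles)),
      split = factor(tbl$split, levels = c("train", "val", "test")),
      fold = tbl$fold,
      diameter = tbl$diameter,
      DI = tbl$DI, TT = tbl$TT, vmax = tbl$vmax, DIR = tbl$DIR,
      image_entry = purrr::map(imgs, "entry"),
      image_exit = purrr::map(imgs, "exit"))
    attr(out, "config") <- config
    attr(out, "illumination_shift") <- shift
    class(out) <- c("miml_dataset", class(out))
    out
  })
}

#' Write / read a generated dataset on disk
#'
#' The on-disk dialect is a `manifest.csv` (columns `cell_id`, `label`,
#' `split`, `fold`, `image_entry_path`, `image_exit_path`, `DI`, `TT`,
#' `vmax`, `DIR`) next to one 8-bit grayscale PNG per crop.
#'
#' @param dataset A `miml_dataset` from [make_dataset()].
#' @param dir Output directory (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   `miml_dataset` tibble.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "miml_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  entry <- file.path("images", paste0(dataset$cell_id, "_entry.png"))
  exitp <- file.path("images", paste0(dataset$cell_id, "_exit.png"))
  for (i in seq_len(nrow(dataset))) {
    png::writePNG(dataset$image_entry[[i]] / 255, file.path(dir, entry[i]))
    png::writePNG(dataset$image_exit[[i]] / 255, file.path(dir, exitp[i]))
  }
  man <- data.frame(cell_id = dataset$cell_id,
                    label = as.character(dataset$label),
                    split = as.character(dataset$split),
                    fold = dataset$fold,
                    image_entry_path = entry, image_exit_path = exitp,
                    DI = dataset$DI, TT = dataset$TT, vmax = dataset$vmax,
                    DIR = dataset$DIR)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  read_png <- function(p) {
    img <- png::readPNG(file.path(dir, p))
    if (length(dim(img)) == 3) img <- img[, , 1]
    img * 255
  }
  out <- tibble(
    cell_id = man$cell_id,
    label = factor(man$label),
    split = factor(man$split, levels = c("train", "val", "test")),
    fold = man$fold,
    DI = man$DI, TT = man$TT, vmax = man$vmax, DIR = man$DIR,
    image_entry = purrr::map(man$image_entry_path, read_png),
    image_exit = purrr::map(man$image_exit_path, read_png))
  class(out) <- c("miml_dataset", class(out))
  out
}
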