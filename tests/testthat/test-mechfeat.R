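test_that("deformation index follows (a-b)/(a+b) with its boundary values", {
  expect_equal(compute_di(5, 5), 0)        # flawless circle
  expect_equal(compute_di(3, 0), 1)        # minor axis of zero
  expect_equal(compute_di(3, 1), 0.5)
  expect_error(compute_di(1, 3), "order the axes")
  expect_error(compute_di(0, 0), "degenerate")
  # bounds and monotonicity: DI in [0,1) and increases as b shrinks
  a <- 10
  bs <- seq(9.5, 0.5, by = -0.5)
  di <- compute_di(rep(a, length(bs)), bs)
  expect_true(all(di >= 0 & di < 1))
  expect_true(all(diff(di) > 0))
})

make_disk_frame <- function(h = 60, w = 80, cx = 45, cy = 25, r = 9,
                            bg = 200, fg = 60) {
  m <- matrix(bg, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- fg
    }
  }
  m
}

test_that("detect_cell finds the largest dark component", {
  expect_null(detect_cell(matrix(128, 40, 40)))
  expect_error(detect_cell(matrix(numeric(0), 0, 0)), "empty")

  fr <- make_disk_frame()
  box <- detect_cell(fr)
  expect_s3_class(box, "bounding_box")
  # box center within 1 px of the disk center (0-based coordinates)
  expect_lt(abs((box$x_min + box$x_max) / 2 - (45 - 0.5)), 1)
  expect_lt(abs((box$y_min + box$y_max) / 2 - (25 - 0.5)), 1)

  # two blobs: keeps the larger
  fr2 <- make_disk_frame(r = 10)
  fr2[5:8, 5:8] <- 60
  box2 <- detect_cell(fr2)
  expect_gt(box2$x_min, 20)
})

test_that("fit_ellipse recovers axes of discrete disks and ellipses", {
  fr <- make_disk_frame(r = 10)           # diameter 20 px
  ell <- fit_ellipse(fr, detect_cell(fr))
  expect_equal(ell$a, 20, tolerance = 0.05 * 20)
  expect_equal(ell$b, 20, tolerance = 0.05 * 20)

  # ellipse with full axes 40 x 10 px
  m <- matrix(200, 60, 80)
  for (i in 1:60) for (j in 1:80) {
    if (((j - 40) / 20)^2 + ((i - 30) / 5)^2 <= 1) m[i, j] <- 60
  }
  ell2 <- fit_ellipse(m, detect_cell(m))
  expect_gte(ell2$a, ell2$b)
  expect_equal(ell2$a, 40, tolerance = 0.05 * 40)
  expect_equal(ell2$b, 10, tolerance = 0.05 * 10)

  # degenerate mask
  m1 <- matrix(200, 20, 20)
  m1[10, 10] <- 0
  box <- structure(list(x_min = 8L, y_min = 8L, x_max = 12L, y_max = 12L),
                   class = "bounding_box")
  expect_error(fit_ellipse(m1, box), "degenerate")
})

# a hand-built track: linear motion at 1000 um/s crossing the constriction
toy_track <- function(geometry = channel_geometry(),
                      times = seq(0, 0.04, by = 0.005),
                      x_um = NULL, di = NULL) {
  if (is.null(x_um)) x_um <- 10 + 2000 * times
  if (is.null(di)) di <- rep(0.5, length(times))
  tr <- tibble::tibble(time = times, x_px = x_um / geometry$pixel_scale,
                       y_px = 30, a_px = 20, b_px = 20 * (1 - di) / (1 + di),
                       DI = di)
  attr(tr, "geometry") <- geometry
  class(tr) <- c("cell_track", class(tr))
  tr
}

test_that("transit features follow their definitions on hand-built tracks", {
  # planes at 40 and 70 um: entry crossed at t = 0.010 s, exit at 0.025 s
  # for x = 20 + 2000 t
  geom30 <- channel_geometry(channel_length = 110, constriction_length = 30)
  tr <- toy_track(geom30, times = seq(0, 0.05, by = 0.005),
                  x_um = 20 + 2000 * seq(0, 0.05, by = 0.005))
  f <- transit_features(tr)
  expect_equal(f$TT, 0.015, tolerance = 1e-12)
  expect_equal(f$vmax, 2000, tolerance = 1e-9)

  # vmax is the maximum per-interval speed inside the constriction
  geom <- channel_geometry()   # planes at 40 and 60 um
  times <- 0:5
  x <- c(38, 41, 42, 45, 47, 75)  # inside-constriction speeds: 1, 3, 2
  tr2 <- toy_track(geom, times = times, x_um = x)
  expect_equal(transit_features(tr2)$vmax, 3)

  # DIR: mean |dDI|/dt of {0, .3, .6, .3, 0} at dt = 1 s
  tr3 <- toy_track(geom, times = 0:4, x_um = c(30, 42, 50, 58, 70),
                   di = c(0, 0.3, 0.6, 0.3, 0))
  expect_equal(transit_features(tr3)$DIR, 0.3, tolerance = 1e-12)

  # stuck cell: never exits
  tr4 <- toy_track(geom, times = 0:4, x_um = c(10, 30, 45, 50, 55))
  expect_error(transit_features(tr4), "stuck")
})

test_that("min-max normalizer fits on train only, clips, and is idempotent", {
  train <- tibble::tibble(DI = c(0.2, 0.5, 0.9), TT = c(2, 4, 6),
                          vmax = c(1, 3, 5))
  stats <- fit_normalizer(train)
  out <- apply_normalizer(train, stats)
  expect_equal(out$TT, c(0, 0.5, 1))
  expect_equal(out$DI, train$DI)          # DI passes through unchanged

  unseen <- tibble::tibble(DI = 0.4, TT = 9, vmax = 0)
  norm_unseen <- apply_normalizer(unseen, stats)
  expect_equal(norm_unseen$TT, 1)         # clipped from above
  expect_equal(norm_unseen$vmax, 0)

  # applying the fitted normalizer twice equals applying it once
  expect_identical(apply_normalizer(out, stats), out)

  bad <- tibble::tibble(TT = c(3, 3, 3), vmax = 1:3)
  expect_error(fit_normalizer(bad), "constant training column 'TT'")
})

test_that("extraction round-trips the renderer's ground truth", {
  # render n transits with varied diameter / DI / speed at default noise and
  # check the extracted features track the animated kinematics
  n <- 60
  geom <- channel_geometry(pixel_scale = 1)
  set.seed(42)
  diam <- rnorm(n, 14, 1.5)
  di <- runif(n, 0.3, 0.75)
  vms <- runif(n, 2000, 6000)
  truth <- NULL
  est <- NULL
  for (i in seq_len(n)) {
    fs <- render_transit(diam[i], di[i], geom, n_frames = 20, noise_sd = 8,
                         seed = i, vmax_um_s = vms[i])
    tt <- fs$truth
    tr_truth <- tibble::tibble(time = tt$time, x_px = tt$x_px, y_px = tt$y_px,
                               a_px = tt$a_px, b_px = tt$b_px, DI = tt$DI)
    attr(tr_truth, "geometry") <- geom
    class(tr_truth) <- c("cell_track", class(tr_truth))
    truth <- rbind(truth, transit_features(tr_truth))
    est <- rbind(est, transit_features(track_transit(fs)))
  }
  for (f in c("DI", "TT", "vmax", "DIR")) {
    expect_gt(cor(truth[[f]], est[[f]]), 0.9)
  }
  # and TT/vmax remain negatively associated in the extracted table
  expect_lt(cor(est$TT, est$vmax), 0)
})
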