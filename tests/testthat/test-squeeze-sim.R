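test_that("spring cells start as regular polygons at mechanical rest", {
  cell <- build_cell(n_nodes = 60, radius = 7.1)
  # polygon area approaches pi r^2
  expect_equal(mimlr:::polygon_area(cell$pos), pi * 7.1^2,
               tolerance = 0.01 * pi * 7.1^2)
  # turning angles all equal 2 pi / n
  p <- cell$pos
  nxt <- c(2:60, 1); prv <- c(60, 1:59)
  e1 <- p - p[prv, ]; e2 <- p[nxt, ] - p
  th <- atan2(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1], rowSums(e1 * e2))
  expect_equal(th, rep(2 * pi / 60, 60), tolerance = 1e-10)
  # zero elastic force at rest
  f <- mimlr:::elastic_forces(cell)
  expect_lt(max(abs(f)), 1e-9)
  expect_error(build_cell(n_nodes = 8), "at least 12")
})

test_that("stretching one edge produces the hand-computed restoring force", {
  cell <- build_cell(n_nodes = 12, radius = 5, Ks = 3, Kb = 0, Ka = 0)
  # displace node 1 radially outward: its two edges stretch
  dir1 <- cell$pos[1, ] / sqrt(sum(cell$pos[1, ]^2) + 1e-300)
  cell$pos[1, ] <- cell$pos[1, ] + 0.4 * (cell$pos[1, ] - c(20, 0)) /
    sqrt(sum((cell$pos[1, ] - c(20, 0))^2))
  f <- mimlr:::elastic_forces(cell)
  # hand computation: sum over the two incident edges of Ks * strain * unit
  hand <- c(0, 0)
  for (j in c(2, 12)) {
    e <- cell$pos[j, ] - cell$pos[1, ]
    len <- sqrt(sum(e^2))
    strain <- (len - cell$rest_len) / cell$rest_len
    hand <- hand + 3 * strain * e / len
  }
  expect_equal(unname(f[1, ]), unname(hand), tolerance = 1e-12)
  expect_true(is.numeric(dir1))
})

test_that("warmup produces a mass-conserving, idempotent flow field", {
  # uniform channel: uniform axial speed
  geo_u <- channel_geometry(gap_height = 30, wide_gap = 30)
  f_u <- warmup_flow(flow_field(geo_u, u0 = 50))
  expect_equal(range(f_u$grid$u), c(50, 50))

  # half-gap constriction doubles the speed inside
  geo_h <- channel_geometry(gap_height = 15, wide_gap = 30)
  f_h <- warmup_flow(flow_field(geo_h, u0 = 50))
  inside <- f_h$grid$x > 45 & f_h$grid$x < 55
  expect_equal(mean(f_h$grid$u[inside]), 100, tolerance = 1e-6)
  outside <- f_h$grid$x < 30
  expect_equal(mean(f_h$grid$u[outside]), 50, tolerance = 1e-6)

  # idempotence
  expect_identical(warmup_flow(f_h)$grid, f_h$grid)
})

test_that("overdamped steps advect, stay stable, and respect the dt bound", {
  geo_u <- channel_geometry(gap_height = 30, wide_gap = 30)
  field <- warmup_flow(flow_field(geo_u, u0 = 40))
  cell <- build_cell(n_nodes = 24, radius = 5, center = c(20, 0))
  # rest cell in (near) zero flow: no displacement
  f0 <- warmup_flow(flow_field(geo_u, u0 = 1e-9))
  dt0 <- 0.5 * mimlr:::stability_dt(cell, f0)
  c2 <- sim_step(cell, f0, dt0)
  expect_equal(c2$pos, cell$pos, tolerance = 1e-9)

  # uniform flow, zero elastic forces: rigid translation at fluid speed
  rigid <- build_cell(n_nodes = 24, radius = 5, Ks = 0, Kb = 0, Ka = 0,
                      center = c(20, 0))
  r2 <- rigid
  for (i in 1:10) r2 <- sim_step(r2, field, 1e-3)
  expect_equal(r2$pos, rigid$pos + cbind(rep(40 * 0.01, 24), 0),
               tolerance = 1e-9)

  expect_error(sim_step(cell, field, 10), "stability bound")
  expect_error(sim_step(cell, field, -1), "positive")
})

test_that("elastic energy decays under overdamped dynamics with the flow off", {
  geo_u <- channel_geometry(gap_height = 30, wide_gap = 30)
  f0 <- warmup_flow(flow_field(geo_u, u0 = 1e-9))
  cell <- build_cell(n_nodes = 24, radius = 6, Ks = 100, Kb = 10, Ka = 5,
                     center = c(20, 0))
  # perturb a few nodes
  cell$pos[1, ] <- cell$pos[1, ] + c(0.8, 0.3)
  cell$pos[13, ] <- cell$pos[13, ] - c(0.5, 0.6)
  e <- numeric(60)
  dt <- 0.5 * mimlr:::stability_dt(cell, f0)
  for (i in seq_along(e)) {
    cell <- sim_step(cell, f0, dt)
    e[i] <- mimlr:::elastic_energy(cell)
  }
  expect_true(all(diff(e) <= 1e-9))
})

test_that("a default cell squeezes through the constriction realistically", {
  field <- warmup_flow(flow_field(channel_geometry(), u0 = 100))
  cell <- build_cell(center = c(20, 0))  # 14.2 um cell, default stiffness
  dt <- 0.9 * mimlr:::stability_dt(cell, field)
  trace <- run_transit(cell, field, dt = dt, record_every = 50)
  expect_true(attr(trace, "exited"))
  expect_true(all(diff(trace$time) > 0))
  # peak DI strictly inside (0.3, area-conserving bound 0.763)
  expect_gt(max(trace$DI), 0.3)
  expect_lt(max(trace$DI), 0.763)
  # velocity peaks inside the constriction
  pl <- mimlr:::constriction_planes(field$geometry)
  x_at_vmax <- trace$x[which.max(trace$v)]
  expect_true(x_at_vmax >= pl["entry"] && x_at_vmax <= pl["exit"])
  # area conservation within 5% over the full transit
  final <- attr(trace, "cell")
  expect_lt(abs(mimlr:::polygon_area(final$pos) / final$rest_area - 1), 0.05)
  # symmetric channel: no systematic vertical drift
  expect_lt(abs(mean(final$pos[, 2])),
            0.01 * field$geometry$wide_gap)

  feats <- trace_to_features(trace)
  expect_true(all(is.finite(unlist(feats))))
  expect_true(all(unlist(feats) > 0))
  # TT equals the difference of interpolated plane crossings (independent
  # recomputation with stats::approx on the trace itself)
  t_in <- approx(trace$x, trace$time, xout = pl[["entry"]])$y
  t_out <- approx(trace$x, trace$time, xout = pl[["exit"]])$y
  expect_equal(feats$TT, t_out - t_in, tolerance = 1e-6)

  # a cell starting downstream is rejected
  late <- build_cell(center = c(70, 0))
  expect_error(run_transit(late, field, dt = dt), "upstream")
})

test_that("non-exited traces carry the flag and refuse feature extraction", {
  field <- warmup_flow(flow_field(channel_geometry(), u0 = 100))
  cell <- build_cell(center = c(20, 0))
  dt <- 0.9 * mimlr:::stability_dt(cell, field)
  short <- run_transit(cell, field, dt = dt, max_steps = 200L,
                       record_every = 50)
  expect_false(attr(short, "exited"))
  expect_error(trace_to_features(short), "did not exit")
})

test_that("peak deformation decreases with membrane stiffness", {
  field <- warmup_flow(flow_field(channel_geometry(), u0 = 100))
  peaks <- vapply(c(5000, 10000, 20000), function(ks) {
    cell <- build_cell(Ks = ks, center = c(20, 0))
    dt <- 0.9 * mimlr:::stability_dt(cell, field)
    max(run_transit(cell, field, dt = dt, record_every = 50)$DI)
  }, 0)
  expect_true(all(diff(peaks) <= 0))
  # a tenfold stiffer cell deforms strictly less than the soft baseline
  expect_lt(peaks[3], peaks[1])
})
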