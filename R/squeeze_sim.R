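# Simplified 2-D stand-in for the full mesh-based membrane/fluid solver:
# a ring of springs (stretching + bending + an area penalty) advected by a
# prescribed mass-conserving channel flow with linear friction coupling.
# All elastic forces are exact gradients of the elastic energy, so the
# overdamped dynamics dissipate energy when the flow is off.

#' Build a spring-ring cell
#'
#' A regular n-gon of membrane nodes connected by stretching springs, with
#' bending springs on the turning angles and a pressure-like area penalty
#' (a bare spring ring does not conserve area).
#'
#' @param n_nodes Number of membrane nodes (at least 12).
#' @param radius Cell radius, µm.
#' @param Ks Stretching coefficient (force per unit strain).
#' @param Kb Bending coefficient (torque per radian of angle deviation).
#' @param Ka Area-penalty coefficient.
#' @param center Initial cell center `c(x, y)`, µm.
#' @return A `spring_cell`.
#' @export
build_cell <- function(n_nodes = 48, radius = 7.1, Ks = 10000, Kb = 100,
                       Ka = 20, center = c(20, 0)) {
  if (n_nodes < 12) abort("`n_nodes` must be at least 12")
  check_number(radius, "radius", lower = 1e-9)
  if (Ks < 0 || Kb < 0 || Ka < 0) abort("coefficients must be non-negative")
  th <- seq(0, 2 * pi, length.out = n_nodes + 1)[-(n_nodes + 1)]
  pos <- cbind(x = center[1] + radius * cos(th),
               y = center[2] + radius * sin(th))
  rest_len <- sqrt(sum((pos[2, ] - pos[1, ])^2))
  structure(
    list(pos = pos, n = n_nodes, Ks = Ks, Kb = Kb, Ka = Ka,
         rest_len = rest_len, rest_angle = 2 * pi / n_nodes,
         rest_area = polygon_area(pos), radius = radius),
    class = "spring_cell"
  )
}

#' @export
print.spring_cell <- function(x, ...) {
  cat(sprintf("<spring_cell> %d nodes, radius %.2f um, Ks %.3g Kb %.3g Ka %.3g\n",
              x$n, x$radius, x$Ks, x$Kb, x$Ka))
  invisible(x)
}

polygon_area <- function(pos) {
  x <- pos[, 1]; y <- pos[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Equivalent-ellipse full axes of a polygon from its area moments (same
# second-moment definition the image pipeline uses).
polygon_ellipse_axes <- function(pos) {
  x <- pos[, 1]; y <- pos[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  mu20 <- iyy / A - cx^2
  mu02 <- ixx / A - cy^2
  mu11 <- ixy / A - cx * cy
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  list(a = 4 * sqrt(ev[1]), b = 4 * sqrt(ev[2]), center = c(cx, cy))
}

perp <- function(v) cbind(-v[, 2], v[, 1])

# Elastic nodal forces: exact negative gradient of
#   E = Ks/2 sum(rest * strain^2) + Kb/2 sum((theta - theta0)^2)
#     + Ka/2 (A - A0)^2
elastic_forces <- function(cell) {
  p <- cell$pos
  n <- cell$n
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  f <- matrix(0, n, 2)

  # stretching
  e <- p[nxt, ] - p
  len <- sqrt(rowSums(e^2))
  strain <- (len - cell$rest_len) / cell$rest_len
  unit <- e / len
  fs <- cell$Ks * strain * unit         # force pulling node i toward node i+1
  f <- f + fs - fs[prv, ]

  # bending on turning angles; with theta_i the turn from edge (i-1, i) to
  # edge (i, i+1) and g = perp(e)/|e|^2 the angle gradient of one edge:
  #   dtheta_i/dp_{i-1} = +g1, dtheta_i/dp_i = -g1 - g2, dtheta_i/dp_{i+1} = +g2
  if (cell$Kb > 0) {
    e1 <- p - p[prv, ]                  # edge arriving at node i
    e2 <- p[nxt, ] - p                  # edge leaving node i
    th <- atan2(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1], rowSums(e1 * e2))
    coef <- cell$Kb * (th - cell$rest_angle)
    g1 <- perp(e1) / rowSums(e1^2)
    g2 <- perp(e2) / rowSums(e2^2)
    fb <- coef * (g1 + g2)              # node i receives -coef * (-g1 - g2)
    fb[prv, ] <- fb[prv, ] - coef * g1
    fb[nxt, ] <- fb[nxt, ] - coef * g2
    f <- f + fb
  }

  # area penalty: F = Ka * (A0 - A) * dA/dp
  if (cell$Ka > 0) {
    A <- polygon_area(p)
    dAx <- (p[nxt, 2] - p[prv, 2]) / 2
    dAy <- (p[prv, 1] - p[nxt, 1]) / 2
    f <- f + cell$Ka * (cell$rest_area - A) * cbind(dAx, dAy)
  }
  f
}

elastic_energy <- function(cell) {
  p <- cell$pos
  n <- cell$n
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  e <- p[nxt, ] - p
  len <- sqrt(rowSums(e^2))
  strain <- (len - cell$rest_len) / cell$rest_len
  es <- 0.5 * cell$Ks * cell$rest_len * sum(strain^2)
  e1 <- p - p[prv, ]
  e2 <- p[nxt, ] - p
  th <- atan2(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1], rowSums(e1 * e2))
  eb <- 0.5 * cell$Kb * sum((th - cell$rest_angle)^2)
  ea <- 0.5 * cell$Ka * (polygon_area(p) - cell$rest_area)^2
  es + eb + ea
}

#' Prescribed channel flow field
#'
#' Plug-like axial flow whose speed scales inversely with the local gap
#' (mass conservation), with the transverse component from incompressibility
#' (`v = -y du/dx`) so that cells funnel into the constriction. Membrane
#' nodes couple to the fluid through a linear friction coefficient.
#'
#' @param geometry A [channel_geometry()].
#' @param u0 Axial speed in the wide channel, µm/s.
#' @param gamma Friction coefficient coupling nodes to the fluid.
#' @param ramp Length of the gap transition ramp, µm.
#' @param wall_k Soft-wall stiffness (restoring velocity per µm of wall
#'   penetration). Walls are compliant, standing in for the lubrication
#'   layer: how far a cell is squeezed by them depends on its elasticity,
#'   so stiffer cells deform less.
#' @return A `flow_field`; run [warmup_flow()] before stepping.
#' @export
flow_field <- function(geometry = channel_geometry(), u0 = 100, gamma = 1,
                       ramp = 5, wall_k = 500) {
  check_number(u0, "u0", lower = 1e-12)
  check_number(gamma, "gamma", lower = 1e-12)
  check_number(wall_k, "wall_k", lower = 0)
  structure(list(geometry = geometry, u0 = u0, gamma = gamma, ramp = ramp,
                 wall_k = wall_k, grid = NULL),
            class = "flow_field")
}

#' Establish the steady-state flow field
#'
#' Evaluates and caches the axial velocity profile and its derivative on a
#' fine grid, emulating the cell-free warmup solve of the full framework.
#' Idempotent: warming up twice gives the identical field.
#'
#' @param field A [flow_field()].
#' @return The field with its `grid` cache filled.
#' @export
warmup_flow <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  g <- field$geometry
  xs <- seq(0, g$channel_length, length.out = 4001)
  gap <- gap_at(xs, g, ramp = field$ramp)
  if (any(gap <= 0)) abort("zero gap in the channel profile")
  u <- field$u0 * g$wide_gap / gap
  dudx <- c(diff(u) / diff(xs), 0)
  dudx <- (c(dudx[1], head(dudx, -1)) + dudx) / 2
  field$grid <- list(x = xs, u = u, dudx = dudx, gap = gap)
  field
}

fluid_velocity <- function(field, pos) {
  if (is.null(field$grid)) abort("call warmup_flow() before stepping")
  gr <- field$grid
  # uniform grid: direct linear interpolation (hot path)
  h <- gr$x[2] - gr$x[1]
  t <- pmin(pmax(pos[, 1] - gr$x[1], 0), gr$x[length(gr$x)] - gr$x[1]) / h
  i <- pmin(floor(t) + 1L, length(gr$x) - 1L)
  w <- t - (i - 1L)
  u <- gr$u[i] * (1 - w) + gr$u[i + 1L] * w
  dudx <- gr$dudx[i] * (1 - w) + gr$dudx[i + 1L] * w
  cbind(u, -pos[, 2] * dudx)
}

# conservative upper bound on the stable step for the overdamped update
stability_dt <- function(cell, field) {
  stiff <- cell$Ks / cell$rest_len +
    cell$Kb / cell$rest_len^2 +
    cell$Ka * cell$rest_area +
    field$wall_k
  0.5 * field$gamma / max(stiff, 1e-12)
}

#' Advance the cell one time step
#'
#' Overdamped update: each node moves with the local fluid velocity plus
#' the elastic force divided by the friction coefficient. Wall contact is a
#' soft normal penalty (nodes slide freely along the wall tangent), with a
#' hard backstop well inside the wall as a safety net.
#'
#' @param cell A `spring_cell`.
#' @param field A warmed-up [flow_field()].
#' @param dt Time step, s; must be below the stability bound for the given
#'   stiffness and friction.
#' @return The updated `spring_cell`.
#' @export
sim_step <- function(cell, field, dt) {
  if (dt <= 0) abort("`dt` must be positive")
  if (dt > stability_dt(cell, field)) {
    abort(sprintf("dt = %g above the stability bound %g for this stiffness",
                  dt, stability_dt(cell, field)))
  }
  vel <- fluid_velocity(field, cell$pos) + elastic_forces(cell) / field$gamma
  half_gap <- gap_at(cell$pos[, 1], field$geometry, ramp = field$ramp) / 2
  overlap <- pmax(abs(cell$pos[, 2]) - half_gap, 0)
  vel[, 2] <- vel[, 2] - field$wall_k * pmin(overlap, 2) * sign(cell$pos[, 2])
  pos <- cell$pos + dt * vel
  # hard backstop: never let a node sink more than a small depth into a wall
  half_new <- gap_at(pos[, 1], field$geometry, ramp = field$ramp) / 2
  cap <- half_new + 0.1 * field$geometry$gap_height
  deep <- abs(pos[, 2]) > cap
  pos[deep, 2] <- sign(pos[deep, 2]) * cap[deep]
  cell$pos <- pos
  A <- polygon_area(pos)
  e <- pos[c(2:cell$n, 1), ] - pos
  strain <- (sqrt(rowSums(e^2)) - cell$rest_len) / cell$rest_len
  if (A < 0.1 * cell$rest_area || max(abs(strain)) > 4) {
    abort("unstable step (membrane self-intersection likely); reduce dt")
  }
  cell
}

#' Run a full transit through the constriction
#'
#' Integrates the overdamped dynamics until the cell's trailing edge (its
#' minimum horizontal coordinate) clears the constriction exit, or until
#' `max_steps` is reached. Records time, cell-center position, deformation
#' index (from the polygon's second-moment equivalent ellipse) and center
#' velocity.
#'
#' @param cell A `spring_cell` starting upstream of the constriction.
#' @param field A warmed-up [flow_field()].
#' @param dt Time step, s; defaults to 90% of the stability bound for the
#'   given stiffness and friction.
#' @param max_steps Step cap.
#' @param record_every Record the trace every this many steps.
#' @return A `transit_trace` tibble (`time`, `x`, `DI`, `v`) with attributes
#'   `exited` (logical) and `geometry`.
#' @export
run_transit <- function(cell, field, dt = NULL, max_steps = 200000L,
                        record_every = 25L) {
  stopifnot(inherits(cell, "spring_cell"), inherits(field, "flow_field"))
  if (is.null(field$grid)) field <- warmup_flow(field)
  if (is.null(dt)) dt <- 0.9 * stability_dt(cell, field)
  pl <- constriction_planes(field$geometry)
  if (min(cell$pos[, 1]) >= pl["entry"]) {
    abort("cell must start upstream of the constriction")
  }
  rec <- list()
  prev_x <- mean(cell$pos[, 1])
  prev_t <- 0
  exited <- FALSE
  for (s in seq_len(max_steps)) {
    cell <- sim_step(cell, field, dt)
    if (s %% record_every == 0L) {
      ax <- polygon_ellipse_axes(cell$pos)
      tnow <- s * dt
      cx <- ax$center[1]
      rec[[length(rec) + 1]] <- c(time = tnow, x = cx,
                                  DI = compute_di(ax$a, ax$b),
                                  v = (cx - prev_x) / (tnow - prev_t))
      prev_x <- cx; prev_t <- tnow
      if (min(cell$pos[, 1]) > pl["exit"]) {
        exited <- TRUE
        break
      }
    }
  }
  out <- as_tibble(as.data.frame(do.call(rbind, rec)))
  attr(out, "exited") <- exited
  attr(out, "geometry") <- field$geometry
  attr(out, "cell") <- cell
  class(out) <- c("transit_trace", class(out))
  out
}

#' Mechanical features from a simulated transit
#'
#' Maps a [run_transit()] trace to the same `(DI, TT, vmax, DIR)` feature
#' definitions the image pipeline uses, so simulator output can augment
#' training tables.
#'
#' @param trace A `transit_trace` with `exited = TRUE`.
#' @param geometry Channel geometry (defaults to the trace's).
#' @return One-row tibble with `DI`, `TT`, `vmax`, `DIR`.
#' @export
trace_to_features <- function(trace, geometry = attr(trace, "geometry")) {
  stopifnot(inherits(trace, "transit_trace"))
  if (!isTRUE(attr(trace, "exited"))) {
    abort("trace did not exit the constriction; features are undefined")
  }
  pl <- constriction_planes(geometry)
  t_in <- unname(crossing_time(trace$time, trace$x, pl[["entry"]]))
  t_out <- unname(crossing_time(trace$time, trace$x, pl[["exit"]]))
  if (is.na(t_in) || is.na(t_out)) {
    abort("trace does not cross both constriction planes")
  }
  inside <- trace$x >= pl["entry"] & trace$x <= pl["exit"]
  vmax <- max(trace$v[inside])
  di <- max(trace$DI[inside])
  window <- trace$time >= t_in & trace$time <= t_out
  di_w <- trace$DI[window]
  t_w <- trace$time[window]
  dir_val <- if (length(di_w) >= 2) mean(abs(diff(di_w)) / diff(t_w)) else NA_real_
  tibble(DI = di, TT = t_out - t_in, vmax = vmax, DIR = dir_val)
}
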