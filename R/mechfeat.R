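#' Deformation index from ellipse axes
#'
#' `DI = (a - b) / (a + b)` for the major and minor full axes `a >= b` of
#' the cell's equivalent ellipse: 0 for a perfect circle, 1 in the limit of
#' a minor axis of zero.
#'
#' @param a,b Major and minor axes (any common length unit); vectorized.
#' @return DI in \[0, 1\].
#' @examples
#' compute_di(3, 1)
#' @export
compute_di <- function(a, b) {
  if (any(a < b)) abort("`a` must be >= `b`: order the axes before calling")
  if (any(b < 0)) abort("axes must be non-negative")
  if (any(a + b <= 0)) abort("degenerate axes: a = b = 0")
  (a - b) / (a + b)
}

# Otsu threshold of an intensity matrix (0-255 scale).
otsu_threshold <- function(frame) {
  h <- tabulate(pmin(pmax(floor(frame), 0), 255) + 1L, nbins = 256L)
  w <- h / sum(h)
  omega <- cumsum(w)
  mu <- cumsum(w * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L
}

# 4-connected component labels of a logical mask, by iterative minimum-label
# propagation (vectorized; converges in O(component diameter) sweeps).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  repeat {
    up <- rbind(lab[-1, , drop = FALSE], 0L)
    dn <- rbind(0L, lab[-nrow(lab), , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], 0L)
    rt <- cbind(0L, lab[, -ncol(lab), drop = FALSE])
    nb <- pmin(ifelse(up > 0, up, .Machine$integer.max),
               ifelse(dn > 0, dn, .Machine$integer.max),
               ifelse(lf > 0, lf, .Machine$integer.max),
               ifelse(rt > 0, rt, .Machine$integer.max))
    new <- ifelse(mask, pmin(lab, nb), 0L)
    new[mask & new == .Machine$integer.max] <- lab[mask & new == .Machine$integer.max]
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

#' Detect the cell in one frame
#'
#' A classical detector: Otsu threshold on the inverted intensity (cells are
#' dark on a bright background), keep connected components of at least
#' `min_area` pixels, and return the bounding box of the largest.
#'
#' @param frame 2-D grayscale matrix (0-255 scale).
#' @param min_area Minimum component area in pixels squared.
#' @return A `bounding_box` list (`x_min`, `y_min`, `x_max`, `y_max`;
#'   0-based, half-open; x along the flow direction) or `NULL` when no
#'   component qualifies.
#' @export
detect_cell <- function(frame, min_area = 20) {
  if (length(frame) == 0) abort("empty frame array")
  if (!is.matrix(frame)) abort("`frame` must be a 2-D matrix")
  thr <- otsu_threshold(frame)
  mask <- frame <= thr
  if (!any(mask)) return(NULL)
  # reject degenerate thresholds on near-uniform frames: a real cell is a
  # coherent dark region well below the background level
  if (diff(range(frame)) < 20) return(NULL)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < min_area) return(NULL)
  keep <- which.max(sizes)
  idx <- which(lab == keep, arr.ind = TRUE)
  structure(
    list(x_min = min(idx[, 2]) - 1L, y_min = min(idx[, 1]) - 1L,
         x_max = max(idx[, 2]), y_max = max(idx[, 1])),
    class = "bounding_box"
  )
}

#' Fit the equivalent ellipse inside a bounding box
#'
#' Thresholds the frame inside the box and computes the second-order central
#' moments of the resulting mask; the full major/minor axes of the
#' equivalent (same-moments solid) ellipse are `4 * sqrt(eigenvalues)` of
#' the normalized covariance.
#'
#' @param frame 2-D grayscale matrix.
#' @param box A `bounding_box` from [detect_cell()].
#' @return List with `a`, `b` (full axes, px; `a >= b`) and `centroid`
#'   (`x`, `y` in 0-based pixel coordinates).
#' @export
fit_ellipse <- function(frame, box) {
  stopifnot(inherits(box, "bounding_box"))
  sub <- frame[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max, drop = FALSE]
  thr <- otsu_threshold(frame)
  mask <- sub <= thr
  if (sum(mask) < 3) abort("degenerate mask: fewer than 3 pixels inside the box")
  idx <- which(mask, arr.ind = TRUE)
  # pixel centers; convert to global 0-based coordinates
  ys <- idx[, 1] - 0.5 + box$y_min
  xs <- idx[, 2] - 0.5 + box$x_min
  cx <- mean(xs); cy <- mean(ys)
  mu20 <- mean((xs - cx)^2) + 1 / 12  # pixel-area correction
  mu02 <- mean((ys - cy)^2) + 1 / 12
  mu11 <- mean((xs - cx) * (ys - cy))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  list(a = 4 * sqrt(ev[1]), b = 4 * sqrt(ev[2]), centroid = c(x = cx, y = cy))
}

#' Track the cell through a frame sequence
#'
#' Runs [detect_cell()] and [fit_ellipse()] on every frame of a rendered (or
#' recorded) transit and assembles the per-frame track used by
#' [transit_features()].
#'
#' @param fseq A `frame_sequence` (see [render_transit()]).
#' @param min_area Minimum component area for detection.
#' @return A `cell_track` tibble: `time`, `x_px`, `y_px`, `a_px`, `b_px`,
#'   `DI`, with the channel geometry attached as an attribute.
#' @export
track_transit <- function(fseq, min_area = 20) {
  stopifnot(inherits(fseq, "frame_sequence"))
  rows <- purrr::map2(fseq$frames, fseq$times, function(fr, tm) {
    box <- detect_cell(fr, min_area)
    if (is.null(box)) return(NULL)
    ell <- fit_ellipse(fr, box)
    tibble(time = tm, x_px = ell$centroid[["x"]], y_px = ell$centroid[["y"]],
           a_px = ell$a, b_px = ell$b, DI = compute_di(ell$a, ell$b))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) < 3) abort("tracking failed: fewer than 3 frames with a detected cell")
  attr(out, "geometry") <- fseq$geometry
  class(out) <- c("cell_track", class(out))
  out
}

# linearly interpolated time at which the centroid crosses plane x = x0
crossing_time <- function(time, x, x0) {
  after <- which(x >= x0)
  if (!length(after) || after[1] == 1) return(NA_real_)
  i <- after[1]
  t0 <- time[i - 1] + (time[i] - time[i - 1]) * (x0 - x[i - 1]) / (x[i] - x[i - 1])
  t0
}

#' Mechanical features of one transit
#'
#' Reduces a [track_transit()] track to the feature vector
#' `m = (DI, TT, vmax, DIR)`:
#' * `TT` — time between the centroid crossing the constriction entry and
#'   exit planes (linearly interpolated between frames), seconds;
#' * `vmax` — maximum per-interval centroid speed over intervals whose
#'   midpoint lies inside the constriction, µm/s;
#' * `DI` — maximum per-frame deformation index inside the constriction;
#' * `DIR` — mean of |dDI|/dt over the transit window, 1/s (deformation and
#'   recovery both contribute).
#'
#' The constriction entry/exit planes come from the channel geometry
#' metadata, not from the images.
#'
#' @param track A `cell_track`.
#' @return One-row tibble with columns `DI`, `TT`, `vmax`, `DIR`.
#' @export
transit_features <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  geometry <- attr(track, "geometry")
  if (is.null(geometry)) abort("track is missing its channel geometry")
  if (nrow(track) < 3) abort("track must have at least 3 frames")
  px <- geometry$pixel_scale
  x_um <- track$x_px * px
  pl <- constriction_planes(geometry)
  t_in <- unname(crossing_time(track$time, x_um, pl[["entry"]]))
  t_out <- unname(crossing_time(track$time, x_um, pl[["exit"]]))
  if (is.na(t_in)) abort("cell never enters the constriction")
  if (is.na(t_out)) abort("stuck cell: centroid never exits the constriction")

  dt <- diff(track$time)
  speed <- abs(diff(x_um)) / dt
  mid <- (x_um[-1] + x_um[-nrow(track)]) / 2
  inside <- mid >= pl["entry"] & mid <= pl["exit"]
  if (!any(inside)) abort("no track interval inside the constriction")
  vmax <- max(speed[inside])

  in_frames <- x_um >= pl["entry"] & x_um <= pl["exit"]
  di <- if (any(in_frames)) max(track$DI[in_frames]) else max(track$DI)

  # widen the transit window by one frame spacing so short transits (few
  # frames between the planes) still yield a defined rate
  pad <- stats::median(dt)
  window <- track$time >= t_in - pad & track$time <= t_out + pad
  if (sum(window) >= 2) {
    di_w <- track$DI[window]
    t_w <- track$time[window]
    dir_val <- mean(abs(diff(di_w)) / diff(t_w))
  } else {
    dir_val <- NA_real_
  }
  tibble(DI = di, TT = t_out - t_in, vmax = vmax, DIR = dir_val)
}

#' Extract features from many transits
#'
#' @param sequences A list of `frame_sequence` objects.
#' @param min_area Minimum detection area.
#' @return Tibble with `cell_id` and the four feature columns.
#' @export
extract_features <- function(sequences, min_area = 20) {
  rows <- purrr::imap(sequences, function(fs, i) {
    f <- transit_features(track_transit(fs, min_area))
    f$cell_id <- if (is.character(i)) i else sprintf("cell_%05d", as.integer(i))
    f
  })
  dplyr::bind_rows(rows)[, c("cell_id", "DI", "TT", "vmax", "DIR")]
}

#' Min-max feature normalization fitted on the training split
#'
#' DI is already on a 0-1 scale and passes through unchanged; transition
#' time, maximum velocity (and DIR when present) are mapped by
#' `(x - min) / (max - min)` with the minima/maxima estimated from the
#' training split only. Applying the fitted stats to unseen data can fall
#' outside \[0, 1\]; such values are clipped.
#'
#' @param train Training-split feature table.
#' @param features Columns to normalize (defaults to all of `TT`, `vmax`,
#'   `DIR` that are present; `DI` is never rescaled).
#' @return A `normalizer_stats` object.
#' @export
fit_normalizer <- function(train, features = intersect(c("TT", "vmax", "DIR"),
                                                       names(train))) {
  stats_list <- lapply(features, function(f) {
    x <- train[[f]]
    if (all(is.na(x))) abort(sprintf("feature '%s' is all-NA", f))
    r <- range(x, na.rm = TRUE)
    if (diff(r) <= 0) abort(sprintf("constant training column '%s' cannot be normalized", f))
    c(min = r[1], max = r[2])
  })
  structure(list(features = features,
                 min = vapply(stats_list, `[[`, 0, "min"),
                 max = vapply(stats_list, `[[`, 0, "max")),
            class = "normalizer_stats")
}

#' @rdname fit_normalizer
#' @param table Feature table to normalize.
#' @param stats A fitted `normalizer_stats`.
#' @export
apply_normalizer <- function(table, stats) {
  stopifnot(inherits(stats, "normalizer_stats"))
  if (isTRUE(attr(table, "normalized"))) return(table)
  for (i in seq_along(stats$features)) {
    f <- stats$features[i]
    if (!f %in% names(table)) next
    x <- (table[[f]] - stats$min[i]) / (stats$max[i] - stats$min[i])
    table[[f]] <- pmin(pmax(x, 0), 1)
  }
  attr(table, "normalized") <- TRUE
  table
}

#' @export
print.normalizer_stats <- function(x, ...) {
  cat("<normalizer_stats>\n")
  for (i in seq_along(x$features)) {
    cat(sprintf("  %-5s min %.4g  max %.4g\n", x$features[i], x$min[i], x$max[i]))
  }
  invisible(x)
}
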