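# Visual trajectory encodings: path-geometry (TRAJ) images with
# traversal-weighted strokes and intersection markers, section-speed (SPEED)
# images, and the binary time-vs-sensor grid (GVFE) baseline.

#' Self-intersection points of a trajectory polyline
#'
#' Finds all crossings between non-adjacent segments of the walked polyline.
#' Shared endpoints of consecutive segments are never intersections, and the
#' meeting of two non-adjacent segments exactly at both their endpoints
#' (e.g. the closure point of a lap) is not counted either; a crossing or a
#' T-touch is. Collinear overlaps have no single crossing point and are
#' skipped. Points closer than \code{tol} are merged.
#'
#' @param traj a \code{trajectory} (>= 2 records).
#' @param tol merge tolerance in meters.
#' @return data.frame with columns \code{x}, \code{y} in meters (0 rows when
#'   the path never crosses itself).
#' @export
find_intersections <- function(traj, tol = 1e-9) {
  stopifnot(nrow(traj) >= 2L)
  px <- traj$x; py <- traj$y
  n_seg <- length(px) - 1L
  pts <- list()
  for (i in seq_len(max(0L, n_seg - 2L))) {
    for (j in (i + 2L):n_seg) {
      p <- segment_crossing(px[i], py[i], px[i + 1L], py[i + 1L],
                            px[j], py[j], px[j + 1L], py[j + 1L])
      if (!is.null(p)) pts[[length(pts) + 1L]] <- p
    }
  }
  if (!length(pts))
    return(data.frame(x = numeric(0), y = numeric(0)))
  m <- do.call(rbind, pts)
  out <- m[1L, , drop = FALSE]
  for (k in seq_len(nrow(m))[-1L]) {
    d2 <- (out[, 1L] - m[k, 1L])^2 + (out[, 2L] - m[k, 2L])^2
    if (all(d2 > tol^2)) out <- rbind(out, m[k, , drop = FALSE])
  }
  data.frame(x = out[, 1L], y = out[, 2L])
}

# Crossing point of segments (a1-a2) and (b1-b2), or NULL. Parametric
# solve; excludes parallel/collinear pairs and pure endpoint-endpoint
# touches.
segment_crossing <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2,
                             eps = 1e-12) {
  rx <- ax2 - ax1; ry <- ay2 - ay1
  sx <- bx2 - bx1; sy <- by2 - by1
  denom <- rx * sy - ry * sx
  scale <- max(abs(rx), abs(ry), abs(sx), abs(sy), 1)
  if (abs(denom) <= eps * scale * scale) return(NULL)
  qpx <- bx1 - ax1; qpy <- by1 - ay1
  t <- (qpx * sy - qpy * sx) / denom
  u <- (qpx * ry - qpy * rx) / denom
  tol <- 1e-9
  if (t < -tol || t > 1 + tol || u < -tol || u > 1 + tol) return(NULL)
  x <- ax1 + t * rx; y <- ay1 + t * ry
  at_a_end <- min(abs(t), abs(1 - t)) <= tol
  at_b_end <- min(abs(u), abs(1 - u)) <= tol
  if (at_a_end && at_b_end) return(NULL)
  c(x, y)
}

#' Render the path-geometry (TRAJ) image of a trajectory
#'
#' The walked path is drawn as a monochrome (white on black) line string.
#' Each undirected edge between two sensor positions is drawn once, with
#' stroke thickness equal to the number of times that edge was walked
#' (capped at \code{weight_cap} px), so paced and lapped paths show up as
#' bold strokes. Every self-intersection of the polyline is overdrawn as a
#' filled red circle whose radius corresponds to \code{circle_radius_m}
#' meters (at least 1 px), highlighting path intricacy.
#'
#' @param traj a \code{trajectory} (>= 2 records) inside the home extent.
#' @param lt a \code{layout_transform}.
#' @param weight_cap maximum stroke thickness in pixels.
#' @param circle_radius_m intersection marker radius in meters.
#' @return a \code{trajectory_image} with encoding \code{"TRAJ"}.
#' @export
render_traj_image <- function(traj, lt, weight_cap = 7L,
                              circle_radius_m = 0.25) {
  stopifnot(nrow(traj) >= 2L)
  if (!all(inside_extent(lt, traj$x, traj$y)))
    stop("trajectory leaves the home bounding box of the layout transform")
  img <- blank_image(lt, "TRAJ")
  key <- function(x1, y1, x2, y2) {
    a <- sprintf("%.6f,%.6f", x1, y1)
    b <- sprintf("%.6f,%.6f", x2, y2)
    if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  }
  counts <- new.env(hash = TRUE, parent = emptyenv())
  segs <- list()
  for (i in seq_len(nrow(traj) - 1L)) {
    if (traj$x[i] == traj$x[i + 1L] && traj$y[i] == traj$y[i + 1L]) next
    k <- key(traj$x[i], traj$y[i], traj$x[i + 1L], traj$y[i + 1L])
    if (is.null(counts[[k]])) {
      counts[[k]] <- 1L
      segs[[length(segs) + 1L]] <-
        c(traj$x[i], traj$y[i], traj$x[i + 1L], traj$y[i + 1L], NA)
      names(segs)[length(segs)] <- k
    } else counts[[k]] <- counts[[k]] + 1L
  }
  for (k in names(segs)) {
    s <- segs[[k]]
    w <- min(counts[[k]], as.integer(weight_cap))
    a <- meters_to_pixels(lt, s[1], s[2])
    b <- meters_to_pixels(lt, s[3], s[4])
    img <- draw_line(img, c(a$col, a$row), c(b$col, b$row),
                     color = c(255L, 255L, 255L), width = w)
  }
  ix <- find_intersections(traj)
  if (nrow(ix) > 0L) {
    rad <- max(1L, as.integer(round(circle_radius_m * lt$scale)))
    for (i in seq_len(nrow(ix))) {
      p <- meters_to_pixels(lt, ix$x[i], ix$y[i])
      img <- draw_disc(img, c(p$col, p$row), rad, color = c(255L, 0L, 0L))
    }
  }
  img
}

# Fixed speed-range palette. The eight ranges cover [0,2), [2,4), [4,6),
# [6,8), [8,10), [10,12), [12,15), [15, Inf) m/s; the seventh is extended to
# 15 m/s so the ranges tile the line while keeping the 15 m/s boundary of
# the top (red) range. Indoor walking lives in the first range; the upper
# ranges are populated by sensor-resolution artifacts.
SPEED_BREAKS <- c(0, 2, 4, 6, 8, 10, 12, 15, Inf)
SPEED_COLORS <- matrix(as.integer(c(
  128, 0, 128,    # purple
  238, 130, 238,  # violet
  0, 0, 255,      # blue
  0, 255, 255,    # cyan
  0, 128, 0,      # green
  255, 255, 0,    # yellow
  255, 165, 0,    # orange
  255, 0, 0)     # red
), ncol = 3L, byrow = TRUE,
  dimnames = list(c("purple", "violet", "blue", "cyan", "green", "yellow",
                    "orange", "red"), c("r", "g", "b")))

#' Discretize a walking speed into its color range
#'
#' @param v speed in m/s (vectorized, each >= 0 and finite).
#' @return data.frame with \code{bin} (1..8), \code{color_name} and the RGB
#'   components \code{r}, \code{g}, \code{b}.
#' @export
speed_bin <- function(v) {
  if (any(!is.finite(v)) || any(v < 0))
    stop("speed must be finite and non-negative")
  bin <- findInterval(v, SPEED_BREAKS, rightmost.closed = FALSE)
  bin <- pmin(bin, 8L)
  data.frame(bin = bin,
             color_name = rownames(SPEED_COLORS)[bin],
             r = SPEED_COLORS[bin, "r"],
             g = SPEED_COLORS[bin, "g"],
             b = SPEED_COLORS[bin, "b"],
             row.names = NULL)
}

#' Render the section-speed (SPEED) image of a trajectory
#'
#' The trajectory is partitioned into sections of steady speed -- one per
#' consecutive record pair -- and each section is drawn as a 1 px stroke
#' colored by its speed range. Sections are drawn in temporal order, so when
#' a path is re-walked the most recent speed of that section determines the
#' color.
#'
#' @param traj a \code{trajectory} (>= 2 records, strictly increasing time).
#' @param lt a \code{layout_transform}.
#' @return a \code{trajectory_image} with encoding \code{"SPEED"}.
#' @export
render_speed_image <- function(traj, lt) {
  stopifnot(nrow(traj) >= 2L)
  if (!all(inside_extent(lt, traj$x, traj$y)))
    stop("trajectory leaves the home bounding box of the layout transform")
  dt <- diff(traj$t)
  if (any(dt <= 0))
    stop("non-increasing timestamps; run clean_positions first")
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  bins <- speed_bin(d / dt)
  img <- blank_image(lt, "SPEED")
  for (i in seq_along(dt)) {
    a <- meters_to_pixels(lt, traj$x[i], traj$y[i])
    b <- meters_to_pixels(lt, traj$x[i + 1L], traj$y[i + 1L])
    img <- draw_line(img, c(a$col, a$row), c(b$col, b$row),
                     color = c(bins$r[i], bins$g[i], bins$b[i]), width = 1L)
  }
  img
}

#' Render the binary time-vs-sensor grid (GVFE) image
#'
#' Baseline encoding: the x axis is the temporal order of sensor firings,
#' the y axis the sensor ordinal. For the k-th fired sensor with ordinal s,
#' pixel (k, s) is set to 1; everything else is 0. The height always equals
#' the sensor-inventory size, whatever segmentation threshold produced the
#' trajectory; the width is chosen from the maximum trajectory length in the
#' corpus.
#'
#' @param sensor_seq integer ordinals of the fired sensors, in order (may be
#'   empty).
#' @param n_sensors sensor-inventory size (image height).
#' @param width image width in pixels; must be >= \code{length(sensor_seq)}
#'   (no truncation).
#' @return a \code{gvfe_image}: 0/1 integer matrix \code{n_sensors x width};
#'   \code{m[s, k] == 1} is the pixel at x = k, y = s.
#' @export
render_gvfe_image <- function(sensor_seq, n_sensors, width) {
  sensor_seq <- as.integer(sensor_seq)
  n_sensors <- as.integer(n_sensors); width <- as.integer(width)
  if (length(sensor_seq) > width)
    stop("sensor sequence (", length(sensor_seq),
         ") longer than image width (", width, ")")
  if (length(sensor_seq) &&
      (min(sensor_seq) < 1L || max(sensor_seq) > n_sensors))
    stop("sensor ordinal out of range 1..", n_sensors)
  m <- matrix(0L, nrow = n_sensors, ncol = width)
  if (length(sensor_seq))
    m[cbind(sensor_seq, seq_along(sensor_seq))] <- 1L
  structure(m, class = c("gvfe_image", "matrix", "array"))
}

#' @export
print.gvfe_image <- function(x, ...) {
  cat(sprintf("<gvfe_image> %d sensors x %d steps, %d firings\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Flatten an RGB image into a binary feature vector
#'
#' Row-major flattening with the three channel values per pixel kept
#' adjacent (R, G, B of pixel (1,1), then pixel (1,2), ...), each value
#' mapped to 1 if > 0 and 0 otherwise. A 100 x 130 canvas yields 39,000
#' features. Binarizing an already-binary vector is a no-op.
#'
#' @param img a \code{trajectory_image} (H x W x 3 array).
#' @return integer 0/1 vector of length \code{3 * W * H}.
#' @export
flatten_binarize <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  v <- as.vector(aperm(unclass(img), c(3L, 2L, 1L)))
  as.integer(v > 0)
}
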