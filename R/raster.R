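# Low-level integer rasterization. No anti-aliasing anywhere: downstream
# binarization (value > 0 -> 1) must see only deliberately drawn pixels.

#' Create an empty RGB trajectory image
#'
#' @param lt a \code{layout_transform} giving the canvas size.
#' @param encoding tag, \code{"TRAJ"} or \code{"SPEED"}.
#' @return a \code{trajectory_image}: integer array \code{height x width x 3}
#'   with values 0..255, background black.
#' @export
blank_image <- function(lt, encoding = "TRAJ") {
  img <- array(0L, dim = c(lt$height, lt$width, 3L))
  structure(img, encoding = encoding, class = "trajectory_image")
}

#' @export
print.trajectory_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<trajectory_image> %s, %d x %d px, %d non-black pixels\n",
              attr(x, "encoding"), d[2], d[1],
              sum(apply(x, c(1, 2), max) > 0)))
  invisible(x)
}

# Pixels on the Bresenham line between two integer endpoints (inclusive).
bresenham <- function(c0, r0, c1, r1) {
  dc <- abs(c1 - c0); dr <- abs(r1 - r0)
  sc <- if (c0 < c1) 1L else -1L
  sr <- if (r0 < r1) 1L else -1L
  err <- dc - dr
  n <- max(dc, dr) + 1L
  cols <- integer(n); rows <- integer(n)
  c <- c0; r <- r0
  for (i in seq_len(n)) {
    cols[i] <- c; rows[i] <- r
    if (c == c1 && r == r1) { cols <- cols[1:i]; rows <- rows[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  cbind(col = cols, row = rows)
}

# Stamp a width x width square around each line pixel: width 1 is the bare
# Bresenham line; growing width never removes pixels (stroke monotonicity).
stroke_offsets <- function(width) {
  lo <- -((width - 1L) %/% 2L)
  hi <- width %/% 2L
  expand.grid(dc = lo:hi, dr = lo:hi)
}

#' Draw a straight line segment on a trajectory image
#'
#' @param img a \code{trajectory_image}.
#' @param from,to integer pixel positions \code{c(col, row)}.
#' @param color integer RGB triple 0..255.
#' @param width stroke thickness in pixels (>= 1).
#' @return the modified image.
#' @export
draw_line <- function(img, from, to, color = c(255L, 255L, 255L),
                      width = 1L) {
  d <- dim(img)
  px <- bresenham(as.integer(from[1]), as.integer(from[2]),
                  as.integer(to[1]), as.integer(to[2]))
  off <- stroke_offsets(as.integer(width))
  cols <- rep(px[, "col"], each = nrow(off)) + off$dc
  rows <- rep(px[, "row"], each = nrow(off)) + off$dr
  ok <- cols >= 1L & cols <= d[2] & rows >= 1L & rows <= d[1]
  cols <- cols[ok]; rows <- rows[ok]
  for (ch in 1:3)
    img[cbind(rows, cols, ch)] <- color[ch]
  img
}

#' Draw a filled circle on a trajectory image
#'
#' @param img a \code{trajectory_image}.
#' @param center integer pixel position \code{c(col, row)}.
#' @param radius radius in pixels (>= 1).
#' @param color integer RGB triple.
#' @return the modified image.
#' @export
draw_disc <- function(img, center, radius, color = c(255L, 0L, 0L)) {
  d <- dim(img)
  radius <- max(1L, as.integer(round(radius)))
  rng <- -radius:radius
  grid <- expand.grid(dc = rng, dr = rng)
  grid <- grid[grid$dc^2 + grid$dr^2 <= radius^2, , drop = FALSE]
  cols <- as.integer(center[1]) + grid$dc
  rows <- as.integer(center[2]) + grid$dr
  ok <- cols >= 1L & cols <= d[2] & rows >= 1L & rows <= d[1]
  cols <- cols[ok]; rows <- rows[ok]
  for (ch in 1:3)
    img[cbind(rows, cols, ch)] <- color[ch]
  img
}

#' Write a trajectory image to PNG
#' @param img a \code{trajectory_image} (or GVFE 0/1 matrix).
#' @param path output file.
#' @export
write_image_png <- function(img, path) {
  if (is.matrix(img)) {
    png::writePNG(img[nrow(img):1, , drop = FALSE] * 1.0, path)
  } else {
    png::writePNG(unclass(img) / 255, path)
  }
  invisible(path)
}
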