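#' Affine map from home coordinates to a fixed raster canvas
#'
#' All trajectory images of a deployment share one canvas covering the whole
#' home, so that the spatial extent of every image is identical and pixel
#' positions are comparable across trajectories. The default 100 x 130 px
#' canvas over a ~10 m x 13 m home gives a uniform scale of about 10 px/m.
#'
#' Meters map to 1-based pixel indices with the origin at the top-left
#' corner of the canvas and the pixel row growing as home \code{y} decreases.
#'
#' @param map a \code{sensor_map} (its bounding box defines the home extent),
#'   or a numeric bbox \code{c(xmin, xmax, ymin, ymax)}.
#' @param width,height canvas size in pixels.
#' @param margin extra border in meters added around the bounding box.
#' @return a \code{layout_transform} list with the scale (px/m) and the
#'   expanded bounding box.
#' @export
make_layout_transform <- function(map, width = 100L, height = 130L,
                                  margin = 0) {
  bb <- if (inherits(map, "sensor_map")) map_bbox(map) else map
  stopifnot(length(bb) == 4L, margin >= 0)
  xmin <- bb[[1]] - margin; xmax <- bb[[2]] + margin
  ymin <- bb[[3]] - margin; ymax <- bb[[4]] + margin
  w_m <- xmax - xmin; h_m <- ymax - ymin
  if (w_m <= 0 || h_m <= 0)
    stop("degenerate (zero-area) bounding box; add a margin")
  scale <- min(width / w_m, height / h_m)
  structure(list(width = as.integer(width), height = as.integer(height),
                 xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 scale = scale),
            class = "layout_transform")
}

#' @export
print.layout_transform <- function(x, ...) {
  cat(sprintf("<layout_transform> %d x %d px over [%.2f, %.2f] x [%.2f, %.2f] m (%.2f px/m)\n",
              x$width, x$height, x$xmin, x$xmax, x$ymin, x$ymax, x$scale))
  invisible(x)
}

#' Map meters to pixel indices and back
#'
#' \code{meters_to_pixels} clamps to the canvas; \code{pixels_to_meters}
#' returns the center of the pixel, so mapping a pixel center back to pixels
#' recovers the same pixel.
#'
#' @param lt a \code{layout_transform}.
#' @param x,y coordinates in meters.
#' @return \code{meters_to_pixels}: data.frame with integer \code{col},
#'   \code{row}; \code{pixels_to_meters}: data.frame with \code{x}, \code{y}.
#' @export
meters_to_pixels <- function(lt, x, y) {
  col <- pmin(pmax(floor((x - lt$xmin) * lt$scale) + 1L, 1L), lt$width)
  row <- pmin(pmax(floor((lt$ymax - y) * lt$scale) + 1L, 1L), lt$height)
  data.frame(col = as.integer(col), row = as.integer(row))
}

#' @rdname meters_to_pixels
#' @param col,row 1-based pixel indices.
#' @export
pixels_to_meters <- function(lt, col, row) {
  data.frame(x = lt$xmin + (col - 0.5) / lt$scale,
             y = lt$ymax - (row - 0.5) / lt$scale)
}

#' Is a point inside the transform's (margin-expanded) home extent?
#' @keywords internal
inside_extent <- function(lt, x, y, tol = 1e-9) {
  x >= lt$xmin - tol & x <= lt$xmax + tol &
    y >= lt$ymin - tol & y <= lt$ymax + tol
}
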