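lt_10x13 <- make_layout_transform(c(0, 10, 0, 13), width = 100L,
                                  height = 130L, margin = 0)

test_that("the layout transform has the expected scale and round-trips", {
  expect_equal(lt_10x13$scale, 10)
  # pixel center round trip over the whole canvas
  px <- expand.grid(col = c(1L, 7L, 50L, 100L), row = c(1L, 65L, 130L))
  mtr <- pixels_to_meters(lt_10x13, px$col, px$row)
  back <- meters_to_pixels(lt_10x13, mtr$x, mtr$y)
  expect_equal(back$col, px$col)
  expect_equal(back$row, px$row)
  # margins push interior points away from the border
  ltm <- make_layout_transform(c(0, 10, 0, 13), 100L, 130L, margin = 0.5)
  p <- meters_to_pixels(ltm, 0, 0)
  expect_gte(p$col, floor(0.5 * ltm$scale))
  expect_lte(p$row, 130 - floor(0.5 * ltm$scale) + 1)
  expect_error(make_layout_transform(c(3, 3, 0, 1), 100L, 130L),
               "degenerate")
})

test_that("polyline self-intersections match the orientation-test oracle", {
  # bow-tie: segments 1 and 3 cross at (1,1)
  tr <- make_traj(0:3, c(0, 2, 2, 0), c(0, 2, 0, 2))
  got <- find_intersections(tr)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$x, got$y), c(1, 1))
  # two-point and L-shaped paths cannot self-intersect
  expect_equal(nrow(find_intersections(make_traj(0:1, c(0, 1), c(0, 1)))), 0L)
  expect_equal(nrow(find_intersections(make_traj(0:2, c(0, 3, 3),
                                                 c(0, 0, 4)))), 0L)
  # random polylines against the oracle
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:10, 1)
    tr <- make_traj(seq_len(n), runif(n, 0, 10), runif(n, 0, 13))
    got <- find_intersections(tr)
    want <- intersections_oracle(tr)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(got) > 0) {
      got_s <- got[order(got$x, got$y), , drop = FALSE]
      want_s <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(got_s$x, unname(want_s[, 1]), tolerance = 1e-9)
      expect_equal(got_s$y, unname(want_s[, 2]), tolerance = 1e-9)
    }
  }
})

test_that("path images weight strokes by traversal count", {
  # single pass: 1 px white stroke, no red
  tr <- make_traj(0:1, c(2, 6), c(5, 5))
  img <- render_traj_image(tr, lt_10x13)
  expect_identical(attr(img, "encoding"), "TRAJ")
  white <- img[, , 1] > 0 & img[, , 2] > 0 & img[, , 3] > 0
  expect_true(any(white))
  expect_equal(sum(img[, , 1] > 0 & img[, , 2] == 0), 0L) # no red-only pixels
  rows_hit <- unique(which(white, arr.ind = TRUE)[, 1])
  expect_length(rows_hit, 1L)   # horizontal 1 px stroke
  # pacing over the same edge three times: 3 px stroke
  tr3 <- make_traj(0:3, c(2, 6, 2, 6), c(5, 5, 5, 5))
  img3 <- render_traj_image(tr3, lt_10x13)
  white3 <- img3[, , 1] > 0 & img3[, , 2] > 0 & img3[, , 3] > 0
  expect_length(unique(which(white3, arr.ind = TRUE)[, 1]), 3L)
  # thickness never decreases with more traversals, and caps
  widths <- vapply(c(5, 7, 9, 12), function(k) {
    trk <- make_traj(seq_len(k + 1),
                     rep(c(2, 6), length.out = k + 1), rep(5, k + 1))
    imgk <- render_traj_image(trk, lt_10x13)
    length(unique(which(imgk[, , 2] > 0, arr.ind = TRUE)[, 1]))
  }, 0L)
  expect_true(all(diff(widths) >= 0))
  expect_lte(max(widths), 7L)
})

test_that("intersection markers are red discs near the crossing point", {
  tr <- make_traj(0:3, c(0, 2, 2, 0) + 4, c(0, 2, 0, 2) + 5)
  img <- render_traj_image(tr, lt_10x13)
  red <- img[, , 1] > 0 & img[, , 2] == 0 & img[, , 3] == 0
  expect_true(any(red))
  hits <- which(red, arr.ind = TRUE)
  center <- meters_to_pixels(lt_10x13, 5, 6)
  expect_lte(abs(mean(hits[, 2]) - center$col), 1.5)
  expect_lte(abs(mean(hits[, 1]) - center$row), 1.5)
  expect_error(render_traj_image(make_traj(0:1, c(0, 99), c(0, 0)),
                                 lt_10x13), "bounding box")
})

test_that("speed ranges map to the fixed color table", {
  b <- speed_bin(c(0, 1.99, 2, 3, 16, 13))
  expect_equal(b$bin, c(1L, 1L, 2L, 2L, 8L, 7L))
  expect_equal(b$color_name[1], "purple")
  expect_equal(b$color_name[4], "violet")
  expect_equal(b$color_name[5], "red")
  expect_equal(unname(unlist(b[5, c("r", "g", "b")])), c(255L, 0L, 0L))
  expect_error(speed_bin(-1), "non-negative")
  expect_error(speed_bin(Inf), "finite")
})

test_that("speed images color sections by range, most recent wins", {
  # uniform 1 m/s: everything purple
  tr <- make_traj(c(0, 2, 4), c(2, 4, 6), c(5, 5, 5))
  img <- render_speed_image(tr, lt_10x13)
  drawn <- which(apply(img, c(1, 2), max) > 0, arr.ind = TRUE)
  expect_true(nrow(drawn) > 0)
  expect_true(all(img[cbind(drawn, 1)] == 128 & img[cbind(drawn, 2)] == 0 &
                    img[cbind(drawn, 3)] == 128))
  # re-walked section at a faster speed overwrites the color
  tr2 <- make_traj(c(0, 4, 4 + 4 / 3), c(2, 6, 2), c(5, 5, 5))
  img2 <- render_speed_image(tr2, lt_10x13)
  drawn2 <- which(apply(img2, c(1, 2), max) > 0, arr.ind = TRUE)
  cols <- unique(t(apply(drawn2, 1, function(rc) img2[rc[1], rc[2], ])))
  expect_equal(nrow(cols), 1L)   # violet everywhere: most recent speed 3 m/s
  expect_equal(unname(cols[1, ]), c(238, 130, 238))
  # two sections in different ranges show exactly those two colors
  tr3 <- make_traj(c(0, 2, 3), c(2, 4, 9), c(5, 5, 5))
  img3 <- render_speed_image(tr3, lt_10x13)
  drawn3 <- which(apply(img3, c(1, 2), max) > 0, arr.ind = TRUE)
  cols3 <- unique(t(apply(drawn3, 1, function(rc) img3[rc[1], rc[2], ])))
  expect_equal(nrow(cols3), 2L)  # purple and blue
  expect_error(render_speed_image(make_traj(c(0, 0), c(1, 2), c(1, 1)),
                                  lt_10x13), "timestamps")
})

test_that("binary grid images place one pixel per firing", {
  g <- render_gvfe_image(c(5, 3, 5, 10, 11, 1), n_sensors = 67, width = 6)
  expect_equal(dim(g), c(67L, 6L))
  on <- which(g == 1L, arr.ind = TRUE)
  on <- on[order(on[, "col"]), ]
  expect_equal(unname(on[, "col"]), 1:6)          # x: temporal order
  expect_equal(unname(on[, "row"]), c(5, 3, 5, 10, 11, 1))  # y: ordinal
  expect_equal(sum(g), 6L)
  # vacuous and counting cases
  expect_equal(sum(render_gvfe_image(integer(0), 67, 10)), 0L)
  set.seed(4)
  s <- sample.int(40, 12)
  expect_equal(sum(render_gvfe_image(s, 40, 20)), 12L)
  expect_error(render_gvfe_image(1:10, 67, 5), "longer")
  expect_error(render_gvfe_image(c(1, 70), 67, 5), "out of range")
})

test_that("grid image height tracks the sensor inventory, not the threshold", {
  co <- generate_cohort(cohort_spec(n_persons = c(healthy = 2, MCI = 2,
                                                  PwD = 2),
                                    trajectories_per_person = 3L, seed = 5))
  for (ts in c(60, 120, 180)) {
    gv <- cohort_gvfe_features(co, t_s = ts)
    expect_equal(gv$n_sensors, 67L)
  }
})

test_that("flattening binarizes pixel channels in row-major order", {
  img <- blank_image(lt_10x13)
  v <- flatten_binarize(img)
  expect_length(v, 39000L)
  expect_true(all(v == 0L))
  # one pure-red pixel at a known location -> exactly one 1, at the R slot
  img[3, 5, 1] <- 200L
  v <- flatten_binarize(img)
  expect_equal(sum(v), 1L)
  expect_equal(v[((3 - 1) * 100 + (5 - 1)) * 3 + 1], 1L)
  # binarization is idempotent: a 0/1 image flattens to itself
  tr <- make_traj(c(0, 2, 5), c(1, 4, 4), c(1, 1, 6))
  img2 <- render_traj_image(tr, lt_10x13)
  bin <- img2
  bin[, , ] <- as.integer(unclass(img2) > 0)
  expect_equal(flatten_binarize(bin), flatten_binarize(img2))
})

test_that("rendering is deterministic", {
  tr <- make_traj(c(0, 2, 5, 9), c(1, 4, 4, 8), c(1, 1, 6, 6))
  expect_identical(render_traj_image(tr, lt_10x13),
                   render_traj_image(tr, lt_10x13))
  expect_identical(render_speed_image(tr, lt_10x13),
                   render_speed_image(tr, lt_10x13))
})

test_that("drawn strokes follow the segment within the stroke width", {
  tr <- make_traj(c(0, 5), c(1, 8), c(2, 11))
  img <- render_traj_image(tr, lt_10x13)
  hits <- which(img[, , 2] > 0, arr.ind = TRUE)
  a <- meters_to_pixels(lt_10x13, 1, 2); b <- meters_to_pixels(lt_10x13, 8, 11)
  # every lit pixel lies within 1 px of the ideal line a->b
  dx <- b$col - a$col; dy <- b$row - a$row
  dist <- abs(dy * (hits[, 2] - a$col) - dx * (hits[, 1] - a$row)) /
    sqrt(dx^2 + dy^2)
  expect_lte(max(dist), 1)
})
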