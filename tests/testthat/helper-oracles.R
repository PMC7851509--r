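# Fixture builders and independent oracle implementations used across the
# suite. Oracles deliberately take a different computational route from the
# package code they check.

make_traj <- function(t, x, y, s_id = NA_character_, person = "T") {
  df <- data.frame(t = t, x = x, y = y, s_id = rep_len(s_id, length(t)),
                   kind = rep_len(NA_character_, length(t)),
                   stringsAsFactors = FALSE)
  attr(df, "person_id") <- person
  attr(df, "traj_index") <- 1L
  class(df) <- c("trajectory", "data.frame")
  df
}

make_history <- function(t, x, y, s_id = NA_character_, person = "H") {
  position_history(data.frame(t = t, x = x, y = y,
                              s_id = rep_len(s_id, length(t)),
                              kind = rep_len(NA_character_, length(t)),
                              stringsAsFactors = FALSE),
                   person_id = person)
}

# Cleaning oracle: re-scan the whole history from the start after every
# single deletion (quadratic, obviously correct reading of the rule).
clean_oracle <- function(h, t_v = 15, t_d = 5) {
  df <- as.data.frame(h)
  repeat {
    n <- nrow(df)
    if (n < 2L) break
    deleted <- FALSE
    for (i in seq_len(n - 1L)) {
      dt <- df$t[i + 1L] - df$t[i]
      d <- sqrt((df$x[i + 1L] - df$x[i])^2 + (df$y[i + 1L] - df$y[i])^2)
      bad <- if (dt <= 0) TRUE else (d / dt > t_v || d > t_d)
      if (bad) {
        df <- df[-(i + 1L), , drop = FALSE]
        deleted <- TRUE
        break
      }
    }
    if (!deleted) break
  }
  rownames(df) <- NULL
  df
}

# Segmentation oracle: group labels by cumulative gap exceedances.
segment_oracle <- function(h, t_s, min_records = 2L) {
  if (nrow(h) == 0L) return(list())
  grp <- cumsum(c(1, as.numeric(diff(h$t) > t_s)))
  out <- split(as.data.frame(h), grp)
  out[vapply(out, nrow, 0L) >= min_records]
}

# --- travel-pattern enumeration oracle -------------------------------------
# Interval predicates plus an explicit greedy episode selection; checks the
# incremental detector against direct interval testing.

is_pacing_interval <- function(s) {
  n <- length(s)
  if (n < 4L || s[1L] == s[2L]) return(FALSE)
  all(s == rep(c(s[1L], s[2L]), length.out = n))
}

is_lapping_interval <- function(s) {
  n <- length(s)
  if (n < 7L) return(FALSE)
  for (c in 3L:((n - 1L) %/% 2L)) {
    if ((n - 1L) %% c != 0L) next
    if (anyDuplicated(s[1:c])) next
    if (all(s == s[((seq_len(n) - 1L) %% c) + 1L])) return(TRUE)
  }
  FALSE
}

pattern_oracle <- function(ids, xy = NULL) {
  keep <- c(TRUE, ids[-1L] != ids[-length(ids)])
  s <- ids[keep]
  if (!is.null(xy)) xy <- xy[keep, , drop = FALSE]
  n <- length(s)
  pacing <- 0L; lapping <- 0L; random <- 0L
  consumed <- logical(n)
  i <- 1L
  while (i <= n) {
    pl <- 0L; ll <- 0L
    for (j in seq(i, n)) {
      if (is_pacing_interval(s[i:j])) pl <- j - i + 1L
      if (is_lapping_interval(s[i:j])) ll <- j - i + 1L
    }
    if (pl > 0L && pl >= ll) {
      pacing <- pacing + 1L; consumed[i:(i + pl - 1L)] <- TRUE; i <- i + pl
    } else if (ll > 0L) {
      lapping <- lapping + 1L; consumed[i:(i + ll - 1L)] <- TRUE; i <- i + ll
    } else i <- i + 1L
  }
  if (any(!consumed)) {
    r <- rle(!consumed)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- starts[k]:ends[k]
      if (length(unique(s[seg])) > 4L) {
        if (is.null(xy)) random <- random + 1L
        else {
          ux <- diff(xy[seg, 1L]); uy <- diff(xy[seg, 2L])
          if (length(ux) >= 2L) {
            dot <- ux[-length(ux)] * ux[-1L] + uy[-length(uy)] * uy[-1L]
            nr <- sqrt(ux^2 + uy^2)
            ang <- acos(pmin(pmax(dot / (nr[-length(nr)] * nr[-1L]), -1), 1)) *
              180 / pi
            if (sum(ang >= 45 - 1e-9) >= 2L) random <- random + 1L
          }
        }
      }
    }
  }
  c(pacing = pacing, lapping = lapping, random = random)
}

# Segment-intersection oracle: orientation tests to decide crossing, then a
# line-line solve for the point; independent of the package's parametric
# routine.
intersections_oracle <- function(traj, tol = 1e-9) {
  ccw <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  px <- traj$x; py <- traj$y
  ns <- length(px) - 1L
  pts <- matrix(numeric(0), 0, 2)
  for (i in seq_len(max(0L, ns - 2L))) for (j in (i + 2L):ns) {
    d1 <- ccw(px[j], py[j], px[j + 1], py[j + 1], px[i], py[i])
    d2 <- ccw(px[j], py[j], px[j + 1], py[j + 1], px[i + 1], py[i + 1])
    d3 <- ccw(px[i], py[i], px[i + 1], py[i + 1], px[j], py[j])
    d4 <- ccw(px[i], py[i], px[i + 1], py[i + 1], px[j + 1], py[j + 1])
    crosses <- ((d1 > tol & d2 < -tol) | (d1 < -tol & d2 > tol)) &&
      ((d3 > tol & d4 < -tol) | (d3 < -tol & d4 > tol))
    touches <- (abs(d1) <= tol || abs(d2) <= tol || abs(d3) <= tol ||
                  abs(d4) <= tol)
    if (!crosses && !touches) next
    a1 <- c(px[i], py[i]); a2 <- c(px[i + 1], py[i + 1])
    b1 <- c(px[j], py[j]); b2 <- c(px[j + 1], py[j + 1])
    r <- a2 - a1; sV <- b2 - b1
    den <- r[1] * sV[2] - r[2] * sV[1]
    if (abs(den) < 1e-12) next
    t <- ((b1[1] - a1[1]) * sV[2] - (b1[2] - a1[2]) * sV[1]) / den
    u <- ((b1[1] - a1[1]) * r[2] - (b1[2] - a1[2]) * r[1]) / den
    if (t < -1e-9 || t > 1 + 1e-9 || u < -1e-9 || u > 1 + 1e-9) next
    at_a <- min(abs(t), abs(1 - t)) <= 1e-9
    at_b <- min(abs(u), abs(1 - u)) <= 1e-9
    if (at_a && at_b) next
    pts <- rbind(pts, a1 + t * r)
  }
  if (nrow(pts) == 0L) return(pts)
  keep <- pts[1, , drop = FALSE]
  for (k in seq_len(nrow(pts))[-1]) {
    if (all((keep[, 1] - pts[k, 1])^2 + (keep[, 2] - pts[k, 2])^2 > 1e-18))
      keep <- rbind(keep, pts[k, ])
  }
  keep
}

# Random noisy position history: a bounded walk plus teleport spikes.
random_noisy_history <- function(seed, n = 40L, p_noise = 0.15) {
  set.seed(seed)
  t <- cumsum(runif(n, 0.5, 3))
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 0, 10); y[1] <- runif(1, 0, 13)
  for (i in 2:n) {
    x[i] <- min(max(x[i - 1] + runif(1, -1.5, 1.5), 0), 10)
    y[i] <- min(max(y[i - 1] + runif(1, -1.5, 1.5), 0), 13)
    if (runif(1) < p_noise) {   # teleport-like misfire
      x[i] <- runif(1, 0, 60)
      y[i] <- runif(1, 0, 60)
    }
  }
  make_history(t, x, y)
}

# A small deterministic sensor map on a 3 x 3 grid.
tiny_map <- function() {
  g <- expand.grid(x = c(0, 2, 4), y = c(0, 2, 4))
  sensor_map(sprintf("S%d", seq_len(nrow(g))), g$x, g$y)
}
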