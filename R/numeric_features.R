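# Numeric feature extraction (NFE) baseline: Martino-Saltzman travel-pattern
# counts (pacing / lapping / random) and low-level motion indicators.

#' Discrete location sequence of a trajectory
#'
#' Pattern detection works on discrete locations. Indoors these are the
#' firing sensors: the trajectory's own sensor ids where present, otherwise
#' the nearest sensor in the map. Consecutive repeats are collapsed (a
#' sensor re-firing in place is not a movement).
#'
#' @param traj a \code{trajectory}.
#' @param map optional \code{sensor_map} for snapping coordinates.
#' @return list with \code{id} (character locations) and \code{x}, \code{y}
#'   (their coordinates), consecutive duplicates collapsed.
#' @export
trajectory_locations <- function(traj, map = NULL) {
  if (!is.null(traj$s_id) && !anyNA(traj$s_id)) {
    id <- as.character(traj$s_id); x <- traj$x; y <- traj$y
  } else if (!is.null(map)) {
    idx <- vapply(seq_len(nrow(traj)), function(i)
      which.min((map$x - traj$x[i])^2 + (map$y - traj$y[i])^2), integer(1))
    id <- map$s_id[idx]; x <- map$x[idx]; y <- map$y[idx]
  } else {
    id <- sprintf("%.6f,%.6f", traj$x, traj$y); x <- traj$x; y <- traj$y
  }
  keep <- c(TRUE, id[-1L] != id[-length(id)])
  list(id = id[keep], x = x[keep], y = y[keep])
}

# Longest alternating run A,B,A,B,... starting at i (in elements).
alternation_length <- function(id, i) {
  n <- length(id)
  if (i + 1L > n || id[i + 1L] == id[i]) return(1L)
  j <- i + 1L
  while (j + 1L <= n && id[j + 1L] == id[j - 1L]) j <- j + 1L
  j - i + 1L
}

# Longest complete-circuit lapping episode starting at i: a cycle of c >= 3
# distinct locations repeated cyclically, cut at the last complete circuit;
# valid only with >= 2 circuits. Returns consumed length in elements (0 if
# no valid episode).
lapping_length <- function(id, i) {
  n <- length(id)
  best <- 0L
  max_c <- (n - i) %/% 2L
  if (max_c < 3L) return(0L)
  for (c in 3L:max_c) {
    if (anyDuplicated(id[i:(i + c - 1L)])) next
    j <- i + c
    while (j <= n && id[j] == id[i + ((j - i) %% c)]) j <- j + 1L
    moves <- (j - 1L) - i
    circuits <- moves %/% c
    if (circuits >= 2L) best <- max(best, circuits * c + 1L)
  }
  best
}

# Number of direction changes (turn of at least `deg` degrees) along a
# sequence of distinct positions.
count_direction_changes <- function(x, y, deg = 45) {
  if (length(x) < 3L) return(0L)
  ux <- diff(x); uy <- diff(y)
  ang <- vector_angles(ux, uy)
  sum(ang >= deg - 1e-9, na.rm = TRUE)
}

# Angles (degrees, in [0, 180]) between successive direction vectors.
vector_angles <- function(ux, uy) {
  n <- length(ux)
  if (n < 2L) return(numeric(0))
  a <- ux[-n]; b <- uy[-n]; cx <- ux[-1L]; cy <- uy[-1L]
  dot <- a * cx + b * cy
  nrm <- sqrt(a^2 + b^2) * sqrt(cx^2 + cy^2)
  cosv <- pmin(pmax(dot / nrm, -1), 1)
  acos(cosv) * 180 / pi
}

#' Count Martino-Saltzman travel-pattern episodes in a trajectory
#'
#' Scans the discrete location sequence left to right, counting
#' non-overlapping maximal episodes, longest match first (pacing preferred
#' on ties):
#' \itemize{
#'   \item \strong{pacing}: at least three consecutive back-and-forth moves
#'     between two locations (A,B,A,B is the shortest valid episode);
#'   \item \strong{lapping}: at least two complete circular movements over a
#'     cycle of at least three distinct locations (A,B,C,A,B,C,A is the
#'     shortest over three);
#'   \item \strong{random}: a leftover stretch (consumed by neither pattern)
#'     that visits more than four distinct locations with at least two
#'     direction changes (turns of >= 45 degrees).
#' }
#' A direct trajectory scores zero on all three.
#'
#' @param traj a \code{trajectory}, or a character vector of location ids
#'   (then \code{x}/\code{y} of the locations may be given for the random
#'   test; without them direction changes cannot be assessed and random
#'   requires only the location-count condition).
#' @param map optional \code{sensor_map} used to snap coordinates.
#' @return named integer vector \code{c(pacing, lapping, random)}.
#' @export
detect_travel_patterns <- function(traj, map = NULL) {
  if (is.character(traj)) {
    keep <- c(TRUE, traj[-1L] != traj[-length(traj)])
    loc <- list(id = traj[keep], x = NULL, y = NULL)
  } else {
    loc <- trajectory_locations(traj, map)
  }
  id <- loc$id
  n <- length(id)
  pacing <- 0L; lapping <- 0L; random <- 0L
  consumed <- logical(n)
  i <- 1L
  while (i <= n) {
    al <- alternation_length(id, i)
    pl <- if (al >= 4L) al else 0L      # >= 3 moves
    ll <- lapping_length(id, i)
    if (pl >= ll && pl > 0L) {
      pacing <- pacing + 1L
      consumed[i:(i + pl - 1L)] <- TRUE
      i <- i + pl
    } else if (ll > 0L) {
      lapping <- lapping + 1L
      consumed[i:(i + ll - 1L)] <- TRUE
      i <- i + ll
    } else {
      i <- i + 1L
    }
  }
  # leftover stretches: maximal runs of unconsumed locations
  if (n > 0L && any(!consumed)) {
    runs <- rle(!consumed)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      seg <- starts[r]:ends[r]
      if (length(unique(id[seg])) > 4L) {
        if (is.null(loc$x)) {
          random <- random + 1L
        } else if (count_direction_changes(loc$x[seg], loc$y[seg]) >= 2L) {
          random <- random + 1L
        }
      }
    }
  }
  c(pacing = pacing, lapping = lapping, random = random)
}

#' Low-level motion indicators of a trajectory
#'
#' Kinematics use the raw records: per-segment speeds, per-junction
#' accelerations and per-junction jerks by successive finite differences
#' (midpoint-time spacing); \code{mean_jerk} is the mean absolute jerk and
#' needs at least 4 records. Geometry uses the distinct-position polyline:
#' the angle at each interior point is the angle between successive
#' direction vectors (straight ahead = 0, U-turn = 180 degrees);
#' \code{sharp_angle_count} counts angles >= 90 degrees,
#' \code{turning_angle_sum} sums the absolute angles (degrees),
#' \code{path_efficiency} is start-to-end distance over walked length (0
#' for a closed path), and \code{straightness} averages the chord-over-arc
#' ratio d(p_i, p_{i+2}) / (d(p_i, p_{i+1}) + d(p_{i+1}, p_{i+2})) over
#' junctions. A statistic with too few points is \code{NA}, never 0.
#'
#' @param traj a \code{trajectory} with >= 2 records and strictly increasing
#'   timestamps.
#' @return list with \code{mean_jerk} (m/s^3), \code{straightness},
#'   \code{sharp_angle_count}, \code{turning_angle_sum} (degrees),
#'   \code{path_efficiency} and \code{n_junctions}.
#' @export
compute_motion_indicators <- function(traj) {
  stopifnot(nrow(traj) >= 2L)
  if (any(diff(traj$t) <= 0))
    stop("timestamps must be strictly increasing; run clean_positions first")
  n <- nrow(traj)
  # kinematics on raw records
  dt <- diff(traj$t)
  dists <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  v <- dists / dt
  tm <- (traj$t[-n] + traj$t[-1L]) / 2       # per-segment midpoint times
  mean_jerk <- NA_real_
  if (n >= 3L) {
    acc <- diff(v) / diff(tm)
    ta <- (tm[-length(tm)] + tm[-1L]) / 2
    if (n >= 4L) {
      jerk <- diff(acc) / diff(ta)
      mean_jerk <- mean(abs(jerk))
    }
  }
  # geometry on distinct positions
  keep <- c(TRUE, dists > 0)
  gx <- traj$x[keep]; gy <- traj$y[keep]
  m <- length(gx)
  sharp <- NA_integer_; turning <- NA_real_; straight <- NA_real_
  n_junctions <- max(0L, m - 2L)
  if (m >= 3L) {
    ang <- vector_angles(diff(gx), diff(gy))
    sharp <- sum(ang >= 90 - 1e-9)
    turning <- sum(ang)
    d01 <- sqrt(diff(gx)^2 + diff(gy)^2)
    chord <- sqrt((gx[-c(1L, 2L)] - gx[-c(m - 1L, m)])^2 +
                  (gy[-c(1L, 2L)] - gy[-c(m - 1L, m)])^2)
    straight <- mean(chord / (d01[-length(d01)] + d01[-1L]))
  } else if (m == 2L) {
    # no junctions: counts/sums over an empty set are 0, averages undefined
    sharp <- 0L; turning <- 0
  }
  plen <- sum(dists)
  path_eff <- if (plen > 0)
    sqrt((traj$x[n] - traj$x[1L])^2 + (traj$y[n] - traj$y[1L])^2) / plen
  else NA_real_
  list(mean_jerk = mean_jerk, straightness = straight,
       sharp_angle_count = sharp, turning_angle_sum = turning,
       path_efficiency = path_eff, n_junctions = n_junctions)
}

#' Daily numeric feature vector (NFE) for one person-day
#'
#' Sums pattern-episode counts and sharp-angle counts over the day's
#' trajectories; averages jerk and straightness over trajectories weighted
#' by junction count (trajectories with an undefined value drop out of the
#' average together with their weight).
#'
#' @param trajs non-empty list of \code{trajectory} objects from one
#'   person-day.
#' @param map optional \code{sensor_map} for location snapping.
#' @return one-row data.frame with columns \code{pacing_count},
#'   \code{lapping_count}, \code{random_count}, \code{mean_jerk},
#'   \code{mean_straightness}, \code{sharp_angle_count}.
#' @export
build_nfe_daily_vector <- function(trajs, map = NULL) {
  if (!length(trajs)) stop("no trajectories for this person-day")
  pats <- vapply(trajs, detect_travel_patterns, integer(3), map = map)
  ind <- lapply(trajs, compute_motion_indicators)
  w <- vapply(ind, function(z) as.numeric(max(z$n_junctions, 1L)), numeric(1))
  wmean <- function(vals) {
    ok <- !is.na(vals)
    if (!any(ok)) return(NA_real_)
    sum(vals[ok] * w[ok]) / sum(w[ok])
  }
  jerks <- vapply(ind, function(z) z$mean_jerk, numeric(1))
  strs <- vapply(ind, function(z) z$straightness, numeric(1))
  sharps <- vapply(ind, function(z) z$sharp_angle_count, numeric(1))
  data.frame(pacing_count = sum(pats["pacing", ]),
             lapping_count = sum(pats["lapping", ]),
             random_count = sum(pats["random", ]),
             mean_jerk = wmean(jerks),
             mean_straightness = wmean(strs),
             sharp_angle_count = sum(sharps, na.rm = TRUE))
}
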