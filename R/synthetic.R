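# Seeded synthetic smart-home locomotion simulator. Emulates a single-story
# ~10 m x 13 m apartment instrumented with 51 ceiling PIR motion sensors and
# 16 door sensors, a single occupant walking class-conditional mixes of
# Martino-Saltzman travel patterns at class-conditional indoor speeds, and a
# noisy positioning system whose teleport-like misfires the cleaning rules
# must remove.

#' Specification of a synthetic cohort
#'
#' The defaults define the simulator's study conditions: 12 cognitively
#' healthy, 10 MCI and 8 PwD persons, 20 trajectories per person-day (a
#' session of a few hours), each a concatenation of 4 travel-pattern
#' episodes drawn from the class's pattern mix. Impairment shifts the mix
#' away from direct travel, slows walking, and reshapes wandering: the MCI
#' profile wanders mostly by pacing, the PwD profile mostly by lapping and
#' random meandering, with intensity (back-and-forth moves per pacing
#' episode, circuits per lap) growing with impairment. Inter-trajectory idle
#' gaps
#' exceed any sensible segmentation threshold by construction, and teleport
#' misfires are injected at a configurable rate per 100 events.
#'
#' @param n_persons named integer vector, persons per class.
#' @param trajectories_per_person trajectories in each person's day.
#' @param episodes_per_trajectory travel-pattern episodes per trajectory.
#' @param pattern_mix 3 x 4 matrix (rows = classes, cols = direct, pacing,
#'   lapping, random), each row summing to 1.
#' @param speed 3 x 2 matrix (rows = classes): mean and sd of segment speed
#'   in m/s (truncated below at 0.2).
#' @param pacing_moves,lapping_circuits per-class episode intensity.
#' @param noise_rate teleport misfires per 100 events.
#' @param time_jitter PIR detection-latency jitter in seconds: each firing
#'   time is perturbed by U(-time_jitter, time_jitter) (order-preserving,
#'   minimum 0.15 s spacing). This reproduces the apparent-speed spread of
#'   real PIR deployments, whose overlapping detection zones inflate
#'   computed speeds well above true walking speed; it never violates the
#'   cleaning thresholds.
#' @param gap_range inter-trajectory idle gap range in seconds (min must
#'   exceed the largest segmentation threshold in use).
#' @param seed master seed.
#' @return a \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_persons = c(healthy = 12L, MCI = 10L, PwD = 8L),
                        trajectories_per_person = 20L,
                        episodes_per_trajectory = 4L,
                        pattern_mix = rbind(
                          healthy = c(0.92, 0.03, 0.03, 0.02),
                          MCI = c(0.55, 0.35, 0.05, 0.05),
                          PwD = c(0.25, 0.10, 0.35, 0.30)),
                        speed = rbind(healthy = c(1.10, 0.15),
                                      MCI = c(0.85, 0.20),
                                      PwD = c(0.60, 0.20)),
                        pacing_moves = c(healthy = 3L, MCI = 6L, PwD = 8L),
                        lapping_circuits = c(healthy = 2L, MCI = 2L, PwD = 4L),
                        noise_rate = 3,
                        time_jitter = 0.5,
                        gap_range = c(200, 600),
                        seed = 1L) {
  stopifnot(all(n_persons >= 0), noise_rate >= 0,
            length(gap_range) == 2L, gap_range[1] > 0,
            gap_range[2] >= gap_range[1])
  colnames(pattern_mix) <- c("direct", "pacing", "lapping", "random")
  if (any(abs(rowSums(pattern_mix) - 1) > 1e-6))
    stop("pattern mix rows must sum to 1")
  structure(list(n_persons = n_persons,
                 trajectories_per_person = as.integer(trajectories_per_person),
                 episodes_per_trajectory = as.integer(episodes_per_trajectory),
                 pattern_mix = pattern_mix, speed = speed,
                 pacing_moves = pacing_moves,
                 lapping_circuits = lapping_circuits,
                 noise_rate = noise_rate, time_jitter = time_jitter,
                 gap_range = gap_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic smart-home layout and sensor map
#'
#' A 10 m x 13 m footprint carries a 7 x 7 lattice of PIR motion sensors
#' (~1.5 m spacing with a small seeded jitter) plus 2 extra hallway motion
#' sensors (51 in total) and 16 door sensors on room boundaries and the
#' perimeter (67 sensors). Every sensor's nearest neighbour is well below
#' 3 m away. Travel-pattern paths are constructed on the complete lattice.
#'
#' @param seed RNG seed for the position jitter.
#' @param width,height home footprint in meters.
#' @return a \code{synthetic_layout}: list with \code{map} (a
#'   \code{sensor_map}), \code{lattice} (data.frame \code{row}, \code{col},
#'   \code{s_id}, \code{x}, \code{y}) and \code{grid_dim}.
#' @export
generate_layout <- function(seed = 1L, width = 10, height = 13) {
  if (width < 6 || height < 8)
    stop("footprint too small for the sensor grid")
  set.seed(seed)
  nr <- 7L; nc <- 7L
  gx <- seq(0.9, width - 0.9, length.out = nc)
  gy <- seq(0.9, height - 0.9, length.out = nr)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  jx <- runif(nrow(grid), -0.15, 0.15)
  jy <- runif(nrow(grid), -0.15, 0.15)
  lat <- data.frame(row = grid$row, col = grid$col,
                    s_id = sprintf("M%03d", seq_len(nrow(grid))),
                    x = gx[grid$col] + jx, y = gy[grid$row] + jy,
                    stringsAsFactors = FALSE)
  extra <- data.frame(row = NA_integer_, col = NA_integer_,
                      s_id = c("M050", "M051"),
                      x = c(width / 2 + runif(1, -0.2, 0.2),
                            width / 2 + runif(1, -0.2, 0.2)),
                      y = c(0.35, height - 0.35),
                      stringsAsFactors = FALSE)
  # door sensors: room boundaries and the perimeter
  door_xy <- rbind(
    c(2.0, 5.0), c(5.0, 5.0), c(8.0, 5.0),        # living-room doorways
    c(2.5, 9.0), c(5.0, 9.0), c(7.5, 9.0),        # upper-room doorways
    c(4.0, 7.0), c(6.0, 7.0),                     # kitchen/bath passage
    c(0.3, 2.5), c(0.3, 11.0),                    # west wall
    c(width - 0.3, 2.5), c(width - 0.3, 11.0),    # east wall
    c(2.5, 0.3), c(7.5, 0.3),                     # entrance wall
    c(2.5, height - 0.3), c(7.5, height - 0.3))   # north wall
  doors <- data.frame(s_id = sprintf("D%03d", seq_len(nrow(door_xy))),
                      x = door_xy[, 1] + runif(nrow(door_xy), -0.1, 0.1),
                      y = door_xy[, 2] + runif(nrow(door_xy), -0.1, 0.1),
                      stringsAsFactors = FALSE)
  map <- sensor_map(c(lat$s_id, extra$s_id, doors$s_id),
                    c(lat$x, extra$x, doors$x),
                    c(lat$y, extra$y, doors$y),
                    c(rep("motion", nrow(lat) + nrow(extra)),
                      rep("door", nrow(doors))))
  # functional locations of the home: occupants walk habitual routes
  # between these, not between arbitrary grid points
  anchors <- rbind(entrance = c(1L, 4L), couch = c(2L, 2L),
                   dining = c(2L, 6L), kitchen = c(4L, 1L),
                   bathroom = c(4L, 4L), bed1 = c(6L, 2L),
                   bed2 = c(6L, 6L), bed3 = c(7L, 4L))
  colnames(anchors) <- c("row", "col")
  structure(list(map = map, lattice = lat, grid_dim = c(nr, nc),
                 anchors = anchors, width = width, height = height),
            class = "synthetic_layout")
}

#' @export
print.synthetic_layout <- function(x, ...) {
  cat(sprintf("<synthetic_layout> %g x %g m, %d sensors (%d motion lattice)\n",
              x$width, x$height, nrow(x$map), nrow(x$lattice)))
  invisible(x)
}

lattice_cell <- function(layout, row, col) {
  i <- which(layout$lattice$row == row & layout$lattice$col == col)
  layout$lattice[i, , drop = FALSE]
}

# Lattice walk between two cells: along the column first, then along the
# row (at most one real turn, so the walk stays 'direct').
l_walk <- function(from, to) {
  rows <- if (from[1] == to[1]) from[1] else from[1]:to[1]
  path <- cbind(row = rows, col = rep(from[2], length(rows)))
  if (from[2] != to[2]) {
    cols <- from[2]:to[2]
    path <- rbind(path, cbind(row = rep(to[1], length(cols) - 1L),
                              col = cols[-1L]))
  }
  path
}

# Perimeter cells of a lattice rectangle, clockwise from the corner.
rect_cycle <- function(r, c, dr, dc) {
  top <- cbind(row = r, col = c:(c + dc))
  right <- cbind(row = (r + 1):(r + dr), col = c + dc)
  bottom <- cbind(row = r + dr, col = (c + dc - 1):c)
  left <- if (dr > 1) cbind(row = (r + dr - 1):(r + 1), col = c)
  rbind(top, right, bottom, left)
}

cells_to_ids <- function(layout, cells) {
  nr <- layout$grid_dim[1]
  idx <- (cells[, "col"] - 1L) * nr + cells[, "row"]
  layout$lattice$s_id[idx]
}

#' Generate one travel-pattern episode as a waypoint sequence
#'
#' Constructs a lattice walk whose discrete location sequence satisfies the
#' corresponding Martino-Saltzman detector predicate: \code{direct} is an
#' L-shaped walk (all pattern counts 0), \code{pacing} alternates between
#' two adjacent cells with >= \code{moves} back-and-forth moves,
#' \code{lapping} walks >= \code{circuits} complete circuits of a
#' rectangular cycle of >= 4 distinct cells, and \code{random} is a
#' rejection-sampled meander over > 4 distinct cells with >= 2 direction
#' changes that the detector classifies as random. Uses the current RNG
#' stream.
#'
#' @param pattern one of \code{"direct"}, \code{"pacing"}, \code{"lapping"},
#'   \code{"random"}.
#' @param layout a \code{synthetic_layout}.
#' @param start optional \code{c(row, col)} starting cell; random if
#'   omitted.
#' @param moves pacing back-and-forth moves (>= 3).
#' @param circuits lapping circuits (>= 2).
#' @return character vector of sensor ids (the episode's waypoints, starting
#'   at \code{start}).
#' @export
generate_pattern_path <- function(pattern = c("direct", "pacing", "lapping",
                                              "random"),
                                  layout, start = NULL, moves = 3L,
                                  circuits = 2L) {
  pattern <- match.arg(pattern)
  nr <- layout$grid_dim[1]; nc <- layout$grid_dim[2]
  if (is.null(start))
    start <- c(sample.int(nr, 1L), sample.int(nc, 1L))
  r <- start[1]; c <- start[2]
  if (pattern == "direct") {
    # walk to a functional location of the home (anchor) far enough away
    anc <- layout$anchors
    ok <- which(abs(anc[, "row"] - r) + abs(anc[, "col"] - c) >= 3L)
    to <- anc[ok[sample.int(length(ok), 1L)], ]
    return(cells_to_ids(layout, l_walk(start, to)))
  }
  if (pattern == "pacing") {
    stopifnot(moves >= 3L)
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
             drop = FALSE]
    b <- nb[sample.int(nrow(nb), 1L), ]
    cells <- matrix(0L, moves + 1L, 2L,
                    dimnames = list(NULL, c("row", "col")))
    for (k in 0:moves)
      cells[k + 1L, ] <- if (k %% 2L == 0L) c(r, c) else b
    return(cells_to_ids(layout, cells))
  }
  if (pattern == "lapping") {
    stopifnot(circuits >= 2L)
    dr <- sample(1:2, 1L); dc <- sample(1:2, 1L)
    r0 <- min(r, nr - dr); c0 <- min(c, nc - dc)
    cyc <- rect_cycle(r0, c0, dr, dc)
    cells <- rbind(cyc[rep(seq_len(nrow(cyc)), circuits), , drop = FALSE],
                   cyc[1L, , drop = FALSE])
    return(cells_to_ids(layout, cells))
  }
  # random: rejection-sample a meander until the detector agrees
  for (try in 1:50) {
    n_steps <- sample(7:12, 1L)
    cells <- matrix(c(r, c), 1L, 2L, dimnames = list(NULL, c("row", "col")))
    cur <- c(r, c)
    for (s in seq_len(n_steps)) {
      nb <- rbind(c(cur[1] - 1, cur[2]), c(cur[1] + 1, cur[2]),
                  c(cur[1], cur[2] - 1), c(cur[1], cur[2] + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
               drop = FALSE]
      cur <- nb[sample.int(nrow(nb), 1L), ]
      cells <- rbind(cells, cur)
    }
    ids <- cells_to_ids(layout, cells)
    idx <- match(ids, layout$lattice$s_id)
    fake <- data.frame(t = seq_along(ids), x = layout$lattice$x[idx],
                       y = layout$lattice$y[idx], s_id = ids)
    cnt <- detect_travel_patterns(structure(fake,
                                            class = c("trajectory",
                                                      "data.frame")))
    if (cnt["random"] >= 1L && cnt["pacing"] == 0L && cnt["lapping"] == 0L)
      return(ids)
  }
  stop("could not sample a random-pattern path on this layout")
}

end_cell <- function(layout, s_id) {
  i <- match(s_id, layout$lattice$s_id)
  c(layout$lattice$row[i], layout$lattice$col[i])
}

#' Simulate one person-day of sensor events
#'
#' Emits a raw event stream: trajectories of concatenated travel-pattern
#' episodes drawn from the class's pattern mix, with per-segment travel
#' times from the class's (truncated normal) speed distribution,
#' inter-trajectory idle gaps drawn from \code{spec$gap_range} (so the
#' segmentation threshold always recovers the true boundaries), and
#' teleport misfires injected at \code{spec$noise_rate} per 100 events:
#' each misfire fires a sensor more than 5 m away 0.1 s after a genuine
#' event, so it violates the cleaning thresholds by construction. Each new
#' trajectory starts where the previous one ended (the occupant idles in
#' place between locomotion episodes).
#'
#' @param class one of \code{COG_CLASSES}.
#' @param spec a [cohort_spec()].
#' @param layout a [generate_layout()] result.
#' @param seed RNG seed for this person-day.
#' @param t0 epoch start time in seconds.
#' @return list with \code{events} (data.frame \code{t}, \code{s_id},
#'   \code{value}, noise included), \code{truth} (per-trajectory
#'   \code{start_t}, \code{end_t}, \code{n_events}), \code{patterns}
#'   (per-trajectory episode counts by type) and \code{noise_t} (times of
#'   injected misfires).
#' @export
simulate_person_day <- function(class, spec, layout, seed,
                                t0 = 1583049600) {
  stopifnot(class %in% COG_CLASSES)
  set.seed(seed)
  mix <- spec$pattern_mix[class, ]
  sp <- spec$speed[class, ]
  pm <- spec$pacing_moves[class]
  lc <- spec$lapping_circuits[class]
  pos <- function(ids) {
    i <- match(ids, layout$map$s_id)
    cbind(layout$map$x[i], layout$map$y[i])
  }
  t <- t0
  cur <- layout$anchors["entrance", ]   # sessions start at the entrance
  ev_t <- numeric(0); ev_id <- character(0)
  truth <- list(); pat_rows <- list()
  for (tr in seq_len(spec$trajectories_per_person)) {
    ids <- character(0)
    counts <- c(direct = 0L, pacing = 0L, lapping = 0L, random = 0L)
    for (ep in seq_len(spec$episodes_per_trajectory)) {
      pat <- sample(colnames(spec$pattern_mix), 1L, prob = mix)
      path <- generate_pattern_path(pat, layout, start = cur,
                                    moves = pm, circuits = lc)
      counts[pat] <- counts[pat] + 1L
      cur <- end_cell(layout, path[length(path)])
      ids <- c(ids, if (length(ids)) path[-1L] else path)
    }
    xy <- pos(ids)
    d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    v <- pmax(rnorm(length(d), sp[1], sp[2]), 0.2)
    times <- t + cumsum(c(0, d / v))
    if (spec$time_jitter > 0) {
      times <- times + runif(length(times), -spec$time_jitter,
                             spec$time_jitter)
      for (k in seq_along(times)[-1L])   # keep firing order, >= 0.15 s apart
        times[k] <- max(times[k], times[k - 1L] + 0.15)
    }
    ev_t <- c(ev_t, times); ev_id <- c(ev_id, ids)
    truth[[tr]] <- data.frame(traj = tr, start_t = times[1L],
                              end_t = times[length(times)],
                              n_events = length(ids))
    pat_rows[[tr]] <- c(traj = tr, counts)
    t <- times[length(times)] + runif(1, spec$gap_range[1],
                                      spec$gap_range[2])
  }
  events <- data.frame(t = ev_t, s_id = ev_id, value = "ON",
                       stringsAsFactors = FALSE)
  # teleport misfires: a far-away sensor firing right after a real event
  noise_t <- numeric(0)
  n_noise <- rbinom(1L, nrow(events), spec$noise_rate / 100)
  if (n_noise > 0L) {
    after <- sort(sample.int(nrow(events) - 1L, min(n_noise,
                                                    nrow(events) - 1L)))
    rows <- lapply(after, function(i) {
      p <- pos(events$s_id[i])
      far <- which(sqrt((layout$map$x - p[1])^2 +
                        (layout$map$y - p[2])^2) > 5.5)
      data.frame(t = events$t[i] + 0.1,
                 s_id = layout$map$s_id[far[sample.int(length(far), 1L)]],
                 value = "ON", stringsAsFactors = FALSE)
    })
    noise <- do.call(rbind, rows)
    noise_t <- noise$t
    events <- rbind(events, noise)
    events <- events[order(events$t), , drop = FALSE]
    rownames(events) <- NULL
  }
  list(events = events, truth = do.call(rbind, truth),
       patterns = as.data.frame(do.call(rbind, pat_rows)),
       noise_t = noise_t)
}

#' Generate a labeled synthetic cohort
#'
#' Builds the layout, then one person-day of events per person with a
#' per-person seed derived from the master seed. The manifest records the
#' master seed, the flattened specification and the per-person seeds, and
#' is byte-identical across runs with the same spec.
#'
#' @param spec a [cohort_spec()] with >= 2 persons in every class.
#' @return a \code{synthetic_cohort}: list with \code{layout}, \code{map},
#'   \code{persons} (data.frame \code{person}, \code{class}, \code{seed}),
#'   \code{days} (per-person [simulate_person_day()] results) and
#'   \code{manifest}.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (any(spec$n_persons < 2L))
    stop("leave-one-person-out needs >= 2 persons per class; got: ",
         paste(names(spec$n_persons), spec$n_persons, collapse = ", "))
  layout <- generate_layout(seed = spec$seed)
  classes <- rep(names(spec$n_persons), spec$n_persons)
  n <- length(classes)
  set.seed(spec$seed)
  person_seeds <- sample.int(.Machine$integer.max - 1L, n)
  persons <- data.frame(person = sprintf("P%03d", seq_len(n)),
                        class = classes, seed = person_seeds,
                        stringsAsFactors = FALSE)
  days <- lapply(seq_len(n), function(i)
    simulate_person_day(persons$class[i], spec, layout,
                        seed = persons$seed[i],
                        t0 = 1583049600 + (i - 1L) * 86400))
  names(days) <- persons$person
  manifest <- paste0("seed=", spec$seed, ";spec=",
                     paste(names(unlist(spec)), unlist(spec), sep = ":",
                           collapse = ","),
                     ";persons=", paste(persons$person, persons$class,
                                        persons$seed, sep = "/",
                                        collapse = ","))
  structure(list(layout = layout, map = layout$map, persons = persons,
                 days = days, manifest = manifest, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d persons (%s), %d trajectories/person\n",
              nrow(x$persons),
              paste(names(x$spec$n_persons), x$spec$n_persons,
                    collapse = ", ", sep = "="),
              x$spec$trajectories_per_person))
  invisible(x)
}

#' Write a cohort to disk as plain CSV/JSON-free text
#'
#' Writes the sensor map, one event CSV per person and a labels CSV into a
#' directory, in the formats the ingestion functions read back.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$map
  write.csv(data.frame(s_id = m$s_id, x = m$x, y = m$y, kind = m$kind),
            file.path(dir, "sensors.csv"), row.names = FALSE, quote = FALSE)
  write.csv(cohort$persons[, c("person", "class")],
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  for (p in cohort$persons$person) {
    ev <- cohort$days[[p]]$events
    write.csv(data.frame(timestamp = format_timestamp(ev$t),
                         s_id = ev$s_id, value = ev$value),
              file.path(dir, paste0("events_", p, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  writeLines(cohort$manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
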