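#' Cleaning thresholds for implausible position readings
#'
#' Position infrastructures misfire: a reading may teleport the inhabitant
#' across the home. Two physical plausibility thresholds remove such records:
#' a maximum speed \code{t_v} between consecutive records (default 15 m/s) and
#' a maximum step distance \code{t_d} (default 5 m; adjacent sensors in a
#' home deployment are closer than 3 m, so a larger jump cannot be a walked
#' path).
#'
#' @param t_v maximum speed in m/s, > 0.
#' @param t_d maximum step distance in m, > 0.
#' @return a \code{cleaning_config} list.
#' @export
cleaning_config <- function(t_v = 15, t_d = 5) {
  stopifnot(is.numeric(t_v), t_v > 0, is.numeric(t_d), t_d > 0)
  structure(list(t_v = t_v, t_d = t_d), class = "cleaning_config")
}

#' Remove implausible position readings
#'
#' Single left-to-right scan with re-comparison: the current survivor is the
#' anchor; the next record is deleted when the speed from the anchor exceeds
#' \code{t_v} or the distance exceeds \code{t_d}, and the anchor is then
#' compared with the next record. A record with zero time difference from the
#' anchor is collapsed when at the same position (duplicate firing) and
#' deleted otherwise (implied infinite speed). The result is a subsequence of
#' the input in which no consecutive pair violates either threshold.
#'
#' @param h a \code{position_history}, sorted by time.
#' @param cfg a [cleaning_config()].
#' @return the cleaned \code{position_history} (possibly empty).
#' @export
clean_positions <- function(h, cfg = cleaning_config()) {
  stopifnot(inherits(h, "position_history"))
  n <- nrow(h)
  if (n <= 1L) return(h)
  keep <- logical(n)
  keep[1L] <- TRUE
  anchor <- 1L
  for (i in 2L:n) {
    dt <- h$t[i] - h$t[anchor]
    dx <- h$x[i] - h$x[anchor]
    dy <- h$y[i] - h$y[anchor]
    d <- sqrt(dx * dx + dy * dy)
    if (dt <= 0) {
      if (d == 0) next            # duplicate firing: collapse
      next                        # zero-time jump: infinite speed, delete
    }
    if (d / dt > cfg$t_v || d > cfg$t_d) next
    keep[i] <- TRUE
    anchor <- i
  }
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  position_history(out, person_id = attr(h, "person_id"))
}

#' Partition a cleaned history into trajectories
#'
#' Consecutive records whose time gap does not exceed \code{t_s} belong to
#' one trajectory; a longer silence closes the trajectory. By default the
#' trajectories are non-overlapping and the next one starts at the first
#' record after the gap; \code{shared_boundary = TRUE} instead seeds each new
#' trajectory with the last record of the previous one. Trajectories with
#' fewer than \code{min_records} records are dropped (a single point has no
#' drawable path or speed).
#'
#' @param h a cleaned \code{position_history}.
#' @param t_s maximum intra-trajectory gap in seconds, > 0 (30--180 s is the
#'   useful range for home monitoring).
#' @param min_records minimum records per retained trajectory (default 2).
#' @param shared_boundary reproduce the shared-record segmentation variant.
#' @return list of \code{trajectory} objects (data.frames like the history,
#'   with attributes \code{person_id} and \code{traj_index}).
#' @export
segment_trajectories <- function(h, t_s = 120, min_records = 2L,
                                 shared_boundary = FALSE) {
  stopifnot(inherits(h, "position_history"))
  if (!is.numeric(t_s) || length(t_s) != 1L || t_s <= 0)
    stop("t_s must be a positive number of seconds")
  n <- nrow(h)
  if (n == 0L) return(list())
  gaps <- diff(h$t)
  breaks <- which(gaps > t_s)          # trajectory ends at index `breaks`
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  if (shared_boundary && length(breaks))
    starts[-1L] <- breaks              # seed with last record of previous
  out <- list()
  k <- 0L
  for (j in seq_along(starts)) {
    if (ends[j] - starts[j] + 1L < min_records) next
    k <- k + 1L
    tr <- h[starts[j]:ends[j], , drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "person_id") <- attr(h, "person_id")
    attr(tr, "traj_index") <- k
    class(tr) <- c("trajectory", "data.frame")
    out[[k]] <- tr
  }
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> person=%s #%s, %d records, %.1f s, %.1f m\n",
              attr(x, "person_id"), attr(x, "traj_index"), nrow(x),
              x$t[nrow(x)] - x$t[1L], path_length(x)))
  invisible(x)
}

#' Total walked length of a trajectory in meters
#' @param traj a \code{trajectory} (or any data.frame with x, y).
#' @return numeric scalar.
#' @export
path_length <- function(traj) {
  if (nrow(traj) < 2L) return(0)
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}
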