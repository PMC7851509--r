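#' @importFrom stats rnorm runif setNames sd aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

# Timestamps are carried internally as numeric seconds since the epoch (UTC),
# which holds millisecond resolution exactly enough for stable round-trips.

#' Parse event timestamps
#'
#' Accepts ISO-8601 date-times (e.g. \code{"2020-08-30 16:46:18.323"}) or
#' plain numeric seconds. Returns numeric seconds since the epoch (UTC).
#'
#' @param x character or numeric vector.
#' @return numeric vector of seconds; \code{NA} where unparseable.
#' @keywords internal
parse_timestamp <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  numlike <- grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", x)
  out[numlike] <- suppressWarnings(as.numeric(x[numlike]))
  iso <- which(!numlike & nzchar(x))
  # strptime per format, merged element-wise: rows that miss one format may
  # still match another, and malformed rows stay NA without poisoning the rest
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS")) {
    if (!length(iso)) break
    p <- as.numeric(strptime(x[iso], fmt, tz = "UTC"))
    hit <- !is.na(p)
    out[iso[hit]] <- p[hit]
    iso <- iso[!hit]
  }
  out
}

#' Format numeric timestamps as ISO-8601 with milliseconds
#'
#' Rounds to the millisecond and formats explicitly; \code{strftime}'s
#' \code{\%OS3} truncates instead of rounding, which breaks round-trips.
#'
#' @param t numeric seconds since the epoch.
#' @return character vector \code{"YYYY-mm-dd HH:MM:SS.mmm"}.
#' @keywords internal
format_timestamp <- function(t) {
  ms <- round(t * 1000)
  secs <- ms %/% 1000
  frac <- ms %% 1000
  paste0(strftime(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                  "%Y-%m-%d %H:%M:%S", tz = "UTC"),
         sprintf(".%03d", frac))
}

#' Load a sensor position table
#'
#' Reads the deployment's sensor map: one row per static sensor with its
#' relative home coordinates in meters. Besides the keyed table, the map
#' carries a stable ordinal index 1..N per sensor (assigned in file order;
#' binary grid encodings index their y axis with it) and the bounding box
#' of all sensors.
#'
#' @param path CSV file with header \code{s_id,x,y[,kind]}; \code{kind} is
#'   \code{"motion"} or \code{"door"} and defaults to \code{"motion"}.
#' @return a \code{sensor_map}: data.frame with columns \code{s_id}, \code{x},
#'   \code{y}, \code{kind}, \code{ordinal} and a \code{bbox} attribute
#'   \code{c(xmin, xmax, ymin, ymax)}.
#' @export
load_sensor_map <- function(path) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("s_id", "x", "y")
  if (!all(req %in% names(df)))
    stop("sensor map must have columns s_id, x, y (got: ",
         paste(names(df), collapse = ", "), ")")
  if (nrow(df) < 1L) stop("sensor map is empty")
  if (!"kind" %in% names(df)) df$kind <- "motion"
  sensor_map(df$s_id, df$x, df$y, df$kind)
}

#' Construct a sensor map from vectors
#'
#' @param s_id character sensor identifiers, unique and non-empty.
#' @param x,y numeric coordinates in meters.
#' @param kind sensor kind, \code{"motion"} or \code{"door"}.
#' @return a \code{sensor_map} (see [load_sensor_map()]).
#' @export
sensor_map <- function(s_id, x, y, kind = "motion") {
  s_id <- as.character(s_id)
  if (any(!nzchar(s_id))) stop("empty sensor id")
  dup <- s_id[duplicated(s_id)]
  if (length(dup))
    stop("duplicate sensor id(s): ", paste(unique(dup), collapse = ", "))
  x <- suppressWarnings(as.numeric(x)); y <- suppressWarnings(as.numeric(y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("non-numeric or non-finite coordinate at row ", bad[1L])
  kind <- rep_len(as.character(kind), length(s_id))
  if (!all(kind %in% c("motion", "door")))
    stop("sensor kind must be 'motion' or 'door'")
  df <- data.frame(s_id = s_id, x = x, y = y, kind = kind,
                   ordinal = seq_along(s_id), stringsAsFactors = FALSE)
  attr(df, "bbox") <- c(xmin = min(x), xmax = max(x),
                        ymin = min(y), ymax = max(y))
  class(df) <- c("sensor_map", "data.frame")
  df
}

#' @export
print.sensor_map <- function(x, ...) {
  bb <- attr(x, "bbox")
  cat(sprintf("<sensor_map> %d sensors (%d motion, %d door), bbox [%.2f, %.2f] x [%.2f, %.2f] m\n",
              nrow(x), sum(x$kind == "motion"), sum(x$kind == "door"),
              bb["xmin"], bb["xmax"], bb["ymin"], bb["ymax"]))
  invisible(x)
}

#' Bounding box of a sensor map
#' @param map a \code{sensor_map}.
#' @return named numeric \code{c(xmin, xmax, ymin, ymax)} in meters.
#' @export
map_bbox <- function(map) attr(map, "bbox")

#' Load a raw sensor event stream
#'
#' Reads timestamped sensor firings in file order. The CSV dialect is
#' comma-separated with a header \code{timestamp,s_id,value}; timestamps
#' are ISO-8601 (millisecond precision) or numeric seconds.
#'
#' @param path CSV file.
#' @param strict if \code{TRUE} (default \code{FALSE}), an unparseable row is
#'   an error naming the row; otherwise malformed rows are skipped with one
#'   warning reporting the count.
#' @return data.frame with columns \code{t} (numeric seconds), \code{s_id},
#'   \code{value}, in file order.
#' @export
load_event_stream <- function(path, strict = FALSE) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("timestamp", "s_id", "value")
  if (!all(req %in% names(df)))
    stop("event stream must have columns timestamp, s_id, value")
  if (nrow(df) == 0L)
    return(data.frame(t = numeric(0), s_id = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  t <- parse_timestamp(df$timestamp)
  bad <- !is.finite(t) | !nzchar(trimws(df$s_id))
  if (any(bad)) {
    if (strict)
      stop("unparseable event at row ", which(bad)[1L],
           " (timestamp '", df$timestamp[which(bad)[1L]], "')")
    warning(sum(bad), " malformed event row(s) skipped")
  }
  data.frame(t = t[!bad], s_id = trimws(df$s_id[!bad]),
             value = trimws(df$value[!bad]), stringsAsFactors = FALSE)
}

# Sensor values that witness presence; OFF/close releases carry no new
# position evidence by default.
ACTIVATION_VALUES <- c("ON", "on", "On", "OPEN", "open", "Open", "ABSENT",
                       "PRESENT", "1", "TRUE", "true")

#' Join events with the sensor map into a position history
#'
#' Each retained event becomes one position record at the firing sensor's
#' coordinates. Output is sorted by timestamp; ties keep file order (stable
#' sort), so repeated application is idempotent.
#'
#' @param events data.frame from [load_event_stream()].
#' @param map a \code{sensor_map}.
#' @param person_id opaque label attached to the history.
#' @param strict if \code{TRUE} an event whose \code{s_id} is absent from the
#'   map is an error naming the id; otherwise such events are skipped with a
#'   warning.
#' @param activation_only if \code{TRUE} (default) only activation values
#'   (ON/open/...) contribute positions; releases (OFF/close) are dropped.
#' @return a \code{position_history}: data.frame with columns \code{t},
#'   \code{x}, \code{y}, \code{s_id}, \code{kind} and attribute
#'   \code{person_id}.
#' @export
to_position_history <- function(events, map, person_id = NA_character_,
                                strict = FALSE, activation_only = TRUE) {
  stopifnot(inherits(map, "sensor_map"))
  if (activation_only && nrow(events) > 0L)
    events <- events[events$value %in% ACTIVATION_VALUES, , drop = FALSE]
  idx <- match(events$s_id, map$s_id)
  if (anyNA(idx)) {
    unknown <- unique(events$s_id[is.na(idx)])
    if (strict)
      stop("unknown sensor id(s) in event stream: ",
           paste(unknown, collapse = ", "))
    warning(sum(is.na(idx)), " event(s) with unknown sensor id skipped (",
            paste(head(unknown, 3L), collapse = ", "), ")")
    keep <- !is.na(idx)
    events <- events[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  h <- data.frame(t = events$t, x = map$x[idx], y = map$y[idx],
                  s_id = events$s_id, kind = map$kind[idx],
                  stringsAsFactors = FALSE)
  ord <- order(h$t)  # radix sort: stable, ties keep stream order
  h <- h[ord, , drop = FALSE]
  rownames(h) <- NULL
  position_history(h, person_id = person_id)
}

#' Construct a position history from a prepared data.frame
#'
#' @param df data.frame with columns \code{t}, \code{x}, \code{y} and
#'   optionally \code{s_id}, \code{kind}; must be sorted by \code{t}.
#' @param person_id opaque label.
#' @return a \code{position_history}.
#' @export
position_history <- function(df, person_id = NA_character_) {
  stopifnot(all(c("t", "x", "y") %in% names(df)))
  if (!"s_id" %in% names(df)) df$s_id <- NA_character_
  if (!"kind" %in% names(df)) df$kind <- NA_character_
  if (is.unsorted(df$t)) stop("position history must be sorted by t")
  rownames(df) <- NULL
  attr(df, "person_id") <- person_id
  class(df) <- c("position_history", "data.frame")
  df
}

#' @export
print.position_history <- function(x, ...) {
  cat(sprintf("<position_history> person=%s, %d records",
              attr(x, "person_id"), nrow(x)))
  if (nrow(x) > 0L)
    cat(sprintf(", span %.1f s", x$t[nrow(x)] - x$t[1L]))
  cat("\n")
  invisible(x)
}

#' Write / read a position history as CSV
#'
#' Timestamps are written as ISO-8601 with milliseconds; a written history
#' re-read with [read_position_history()] reproduces the original records
#' exactly at millisecond precision.
#'
#' @param h a \code{position_history}.
#' @param path CSV file path.
#' @export
write_position_history <- function(h, path) {
  out <- data.frame(timestamp = format_timestamp(h$t), x = h$x, y = h$y,
                    s_id = h$s_id, kind = h$kind, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_position_history
#' @param person_id label for the loaded history.
#' @export
read_position_history <- function(path, person_id = NA_character_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  h <- data.frame(t = parse_timestamp(df$timestamp),
                  x = as.numeric(df$x), y = as.numeric(df$y),
                  s_id = as.character(df$s_id), kind = as.character(df$kind),
                  stringsAsFactors = FALSE)
  position_history(h, person_id = person_id)
}
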