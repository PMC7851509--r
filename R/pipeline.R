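# Glue from raw event streams to classifier-ready feature matrices.

#' Preprocess one person's event stream into trajectories
#'
#' Joins events with the sensor map, removes implausible readings and
#' segments the cleaned history.
#'
#' @param events event data.frame (\code{t}, \code{s_id}, \code{value}).
#' @param map a \code{sensor_map}.
#' @param t_s segmentation threshold in seconds.
#' @param cfg a [cleaning_config()].
#' @param person_id label for the history.
#' @return list of \code{trajectory} objects.
#' @export
events_to_trajectories <- function(events, map, t_s = 120,
                                   cfg = cleaning_config(),
                                   person_id = NA_character_) {
  h <- to_position_history(events, map, person_id = person_id)
  h <- clean_positions(h, cfg)
  segment_trajectories(h, t_s = t_s)
}

#' Build classifier-ready image-pair features for a cohort
#'
#' Runs the full front of the pipeline on every person: event stream ->
#' cleaned history -> trajectories -> path-geometry and section-speed
#' images -> flattened binarized feature vectors. All images share one
#' layout transform derived from the sensor map, so train and test rasters
#' have the same extent. Feature matrices are sparse (most pixels of a
#' trajectory image are background).
#'
#' @param cohort a \code{synthetic_cohort}, or a named list of event
#'   data.frames plus \code{map}/labels supplied separately.
#' @param t_s segmentation threshold in seconds.
#' @param width,height canvas size in pixels.
#' @param cfg a [cleaning_config()].
#' @return list with sparse matrices \code{traj_x} and \code{speed_x}
#'   (rows = trajectories, \code{3 * width * height} columns),
#'   \code{person}, \code{label}, \code{trajectories} (the trajectory
#'   objects) and the shared \code{transform}.
#' @export
cohort_features <- function(cohort, t_s = 120, width = 100L, height = 130L,
                            cfg = cleaning_config()) {
  lt <- make_layout_transform(cohort$map, width = width, height = height,
                              margin = 0.5)
  rows_t <- list(); rows_s <- list()
  person <- character(0); label <- character(0)
  trajs <- list()
  for (i in seq_len(nrow(cohort$persons))) {
    p <- cohort$persons$person[i]
    tl <- events_to_trajectories(cohort$days[[p]]$events, cohort$map,
                                 t_s = t_s, cfg = cfg, person_id = p)
    for (tr in tl) {
      k <- length(trajs) + 1L
      trajs[[k]] <- tr
      rows_t[[k]] <- which(flatten_binarize(render_traj_image(tr, lt)) > 0L)
      rows_s[[k]] <- which(flatten_binarize(render_speed_image(tr, lt)) > 0L)
      person <- c(person, p)
      label <- c(label, cohort$persons$class[i])
    }
  }
  n <- length(trajs)
  d <- 3L * as.integer(width) * as.integer(height)
  as_sparse <- function(rows) {
    Matrix::sparseMatrix(
      i = rep(seq_len(n), lengths(rows)),
      j = unlist(rows), x = 1, dims = c(n, d))
  }
  list(traj_x = as_sparse(rows_t), speed_x = as_sparse(rows_s),
       person = person, label = label, trajectories = trajs,
       transform = lt)
}

#' Daily numeric feature table for a cohort
#'
#' The tabular baseline: one row per person-day with Martino-Saltzman
#' pattern counts and motion indicators, consumable by any tabular
#' classifier.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param t_s segmentation threshold in seconds.
#' @return data.frame with one labeled row per person.
#' @export
cohort_nfe_table <- function(cohort, t_s = 120) {
  rows <- lapply(seq_len(nrow(cohort$persons)), function(i) {
    p <- cohort$persons$person[i]
    tl <- events_to_trajectories(cohort$days[[p]]$events, cohort$map,
                                 t_s = t_s, person_id = p)
    cbind(data.frame(person = p, class = cohort$persons$class[i],
                     stringsAsFactors = FALSE),
          build_nfe_daily_vector(tl, map = cohort$map))
  })
  do.call(rbind, rows)
}

#' Reference tabular classification of daily numeric features
#'
#' The comparison baseline for the image-pair classifier: a random forest
#' on the per-person-day numeric feature vectors, evaluated
#' leave-one-person-out (each person-day is one labeled row, so each fold
#' holds out one row). Undefined indicator values are imputed with the
#' training-fold median.
#'
#' @param nfe data.frame from [cohort_nfe_table()] (columns \code{person},
#'   \code{class}, features).
#' @param seed RNG seed for the forest.
#' @return list with the leave-one-out \code{eval_report} and the
#'   per-person predictions.
#' @export
nfe_reference_classifier <- function(nfe, seed = 1L) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("nfe_reference_classifier needs the randomForest package")
  feats <- setdiff(names(nfe), c("person", "class"))
  preds <- character(nrow(nfe))
  for (i in seq_len(nrow(nfe))) {
    tr <- nfe[-i, , drop = FALSE]
    te <- nfe[i, , drop = FALSE]
    for (f in feats) {  # median-impute undefined indicators per fold
      med <- stats::median(tr[[f]], na.rm = TRUE)
      tr[[f]][is.na(tr[[f]])] <- med
      te[[f]][is.na(te[[f]])] <- med
    }
    set.seed(seed + i)
    fit <- randomForest::randomForest(
      x = tr[, feats, drop = FALSE],
      y = factor(tr$class, levels = COG_CLASSES))
    preds[i] <- as.character(stats::predict(fit, te[, feats, drop = FALSE]))
  }
  list(report = evaluate_cohort(setNames(preds, nfe$person),
                                setNames(nfe$class, nfe$person)),
       predictions = data.frame(person = nfe$person, truth = nfe$class,
                                predicted = preds,
                                stringsAsFactors = FALSE))
}

#' Binary grid (GVFE) feature matrix for a cohort
#'
#' Encodes each trajectory's sensor-firing sequence as a flattened binary
#' time-vs-sensor image. The width is the maximum trajectory length over
#' the cohort for this segmentation threshold; the height is always the
#' full sensor inventory.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param t_s segmentation threshold in seconds.
#' @return list with sparse \code{x} (rows = trajectories), \code{person},
#'   \code{label}, \code{width}, \code{n_sensors}.
#' @export
cohort_gvfe_features <- function(cohort, t_s = 120) {
  map <- cohort$map
  seqs <- list(); person <- character(0); label <- character(0)
  for (i in seq_len(nrow(cohort$persons))) {
    p <- cohort$persons$person[i]
    tl <- events_to_trajectories(cohort$days[[p]]$events, map,
                                 t_s = t_s, person_id = p)
    for (tr in tl) {
      seqs[[length(seqs) + 1L]] <- map$ordinal[match(tr$s_id, map$s_id)]
      person <- c(person, p)
      label <- c(label, cohort$persons$class[i])
    }
  }
  width <- max(lengths(seqs))
  n_sensors <- nrow(map)
  idx <- lapply(seqs, function(s)
    which(as.vector(render_gvfe_image(s, n_sensors, width)) > 0L))
  x <- Matrix::sparseMatrix(i = rep(seq_along(idx), lengths(idx)),
                            j = unlist(idx), x = 1,
                            dims = c(length(idx), n_sensors * width))
  list(x = x, person = person, label = label, width = width,
       n_sensors = n_sensors)
}
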