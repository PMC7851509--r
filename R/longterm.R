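# Long-term analysis: aggregate per-trajectory class predictions into a
# per-person hypothesis of diagnosis, and evaluate cohorts with
# leave-one-person-out cross-validation and macro-averaged metrics.

#' Long-term hypothesis of diagnosis by majority vote
#'
#' Counts the per-trajectory class predictions accumulated over the
#' observation window and returns the most frequent class. A tie is broken
#' toward the more impaired class (PwD > MCI > healthy) and flagged:
#' clinically conservative and deterministic.
#'
#' @param vtc non-empty character vector of per-trajectory predictions
#'   (values among \code{COG_CLASSES}).
#' @return list with \code{class} (the hypothesis), \code{counts} (named
#'   table over the three classes) and \code{tie} (logical).
#' @export
long_term_diagnosis <- function(vtc) {
  if (!length(vtc)) stop("empty prediction history")
  if (!all(vtc %in% COG_CLASSES))
    stop("predictions must be among: ", paste(COG_CLASSES, collapse = ", "))
  counts <- table(factor(vtc, levels = COG_CLASSES))
  top <- which(counts == max(counts))
  list(class = COG_CLASSES[max(top)], counts = counts,
       tie = length(top) > 1L)
}

#' Leave-one-person-out folds
#'
#' Every person is the test subject exactly once; the remaining persons form
#' the training pool, so no person contributes to both sides of a fold. The
#' validation subset (10% of each class of the training persons'
#' trajectories, seeded) is drawn later, at training time, by
#' [train_model()]'s stratified hold-out.
#'
#' @param persons character person identifiers (>= 2, unique).
#' @param labels class label per person.
#' @return list of folds, each \code{list(test, train)} of person ids.
#'   Errors if removing a test person empties its class in the training
#'   pool, naming the fold.
#' @export
lopo_split <- function(persons, labels) {
  stopifnot(length(persons) >= 2L, !anyDuplicated(persons),
            length(labels) == length(persons))
  lapply(seq_along(persons), function(i) {
    train <- persons[-i]
    missing <- setdiff(unique(labels), unique(labels[-i]))
    if (length(missing))
      stop("fold ", i, " (test person ", persons[i], "): class '",
           missing[1L], "' vanishes from the training pool")
    list(test = persons[i], train = train)
  })
}

#' Macro-averaged evaluation of per-person diagnoses
#'
#' Builds the confusion matrix over the three classes and reports per-class
#' precision, recall and F1 plus their unweighted (macro) means. A metric
#' with a zero denominator is \code{NA} ("n/a"), never coerced to 0, and
#' propagates into the macro mean; a class with neither true nor predicted
#' instances is dropped from the macro averages entirely.
#'
#' @param predictions named character vector (or data.frame with
#'   \code{person}, \code{class}) of predicted classes per person.
#' @param truths named character vector of true classes for the same
#'   persons.
#' @param classes class universe (default the three cognitive classes).
#' @return an \code{eval_report} list: \code{confusion} (rows = truth),
#'   \code{per_class} data.frame, \code{macro_precision},
#'   \code{macro_recall}, \code{macro_f1}.
#' @export
evaluate_cohort <- function(predictions, truths, classes = COG_CLASSES) {
  if (is.data.frame(predictions))
    predictions <- setNames(predictions$class, predictions$person)
  if (is.data.frame(truths))
    truths <- setNames(truths$class, truths$person)
  if (!is.null(names(predictions)) && !is.null(names(truths))) {
    if (!setequal(names(predictions), names(truths)))
      stop("prediction and truth person sets differ")
    predictions <- predictions[names(truths)]
  } else if (length(predictions) != length(truths)) {
    stop("prediction and truth lengths differ")
  }
  conf <- table(truth = factor(truths, levels = classes),
                predicted = factor(predictions, levels = classes))
  tp <- diag(conf)
  pred_n <- colSums(conf)
  true_n <- rowSums(conf)
  precision <- ifelse(pred_n > 0, tp / pred_n, NA_real_)
  recall <- ifelse(true_n > 0, tp / true_n, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(is.na(precision) | is.na(recall), NA_real_, 0))
  present <- pred_n > 0 | true_n > 0
  macro <- function(x) if (any(present)) mean(x[present]) else NA_real_
  structure(list(
    confusion = conf,
    per_class = data.frame(class = classes, precision = as.numeric(precision),
                           recall = as.numeric(recall), f1 = as.numeric(f1),
                           row.names = NULL),
    macro_precision = macro(precision),
    macro_recall = macro(recall),
    macro_f1 = macro(f1)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$confusion)
  print(x$per_class, digits = 3)
  cat(sprintf("macro: precision %.3f | recall %.3f | F1 %.3f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Leave-one-person-out evaluation of the full classification pipeline
#'
#' For each fold, trains the two-branch MLP on the training persons'
#' trajectory image pairs (with a seeded 10%-per-class validation hold-out
#' for early stopping), classifies the held-out person's trajectories, and
#' aggregates them into a long-term diagnosis by majority vote. Reports
#' both the per-person (long-term) and the pooled per-trajectory
#' evaluation, so the benefit of long-term aggregation can be measured.
#'
#' @param features list with \code{traj_x}, \code{speed_x} (feature
#'   matrices, rows = trajectories), \code{person} (person id per row) and
#'   \code{label} (class per row).
#' @param cfg a [train_config()]; fold f trains with seed
#'   \code{cfg$seed + f}.
#' @param spec optional \code{mlp_spec}; defaults to the two-input MLP
#'   sized to the feature matrices.
#' @param verbose print one line per fold.
#' @return list with \code{longterm} and \code{trajectory}
#'   (\code{eval_report}s), \code{per_person} (data.frame of diagnosis vs
#'   truth, with tie flags) and \code{trajectory_predictions}.
#' @export
run_lopo_evaluation <- function(features, cfg = train_config(),
                                spec = NULL, verbose = FALSE) {
  person <- as.character(features$person)
  label <- as.character(features$label)
  ptab <- unique(data.frame(person = person, label = label,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(ptab$person))
    stop("a person has inconsistent labels")
  folds <- lopo_split(ptab$person, ptab$label)
  if (is.null(spec))
    spec <- build_two_input_mlp(input_dim = ncol(features$traj_x))
  diag_rows <- list()
  traj_pred <- character(length(person))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    tr <- person %in% fold$train
    te <- person == fold$test
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- train_model(spec, features$traj_x[tr, , drop = FALSE],
                         features$speed_x[tr, , drop = FALSE],
                         label[tr], fold_cfg)
    pred <- predict_trajectory(model, features$traj_x[te, , drop = FALSE],
                               features$speed_x[te, , drop = FALSE])
    traj_pred[te] <- pred$class
    dg <- long_term_diagnosis(pred$class)
    diag_rows[[f]] <- data.frame(person = fold$test,
                                 truth = ptab$label[ptab$person == fold$test],
                                 diagnosis = dg$class, tie = dg$tie,
                                 n_traj = sum(te), epochs = nrow(model$history),
                                 stringsAsFactors = FALSE)
    if (verbose)
      cat(sprintf("fold %2d/%d person=%s truth=%s -> %s (%d trajectories, %d epochs)\n",
                  f, length(folds), fold$test, diag_rows[[f]]$truth,
                  dg$class, sum(te), nrow(model$history)))
  }
  per_person <- do.call(rbind, diag_rows)
  list(longterm = evaluate_cohort(setNames(per_person$diagnosis,
                                           per_person$person),
                                  setNames(per_person$truth,
                                           per_person$person)),
       trajectory = evaluate_cohort(traj_pred, label),
       per_person = per_person,
       trajectory_predictions = data.frame(person = person, truth = label,
                                           predicted = traj_pred,
                                           stringsAsFactors = FALSE))
}
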