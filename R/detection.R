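# Per-sample class decoding, the consecutive-sample detection rule, trial
# outcome labelling and aggregation into MDT / Sensitivity / Specificity /
# balanced Accuracy.

#' Decode network outputs into W / P / NA classes
#'
#' A sample is assigned the class of the most active output unit if that
#' activity reaches `threshold`; an exact tie between the two units, or no
#' unit reaching the threshold, gives the uncertainty class `NA`.
#'
#' @param raw 2 x T matrix of network outputs (row 1 walking, row 2
#'   perturbation).
#' @param threshold activity threshold (default 0.5).
#' @return Character vector over `"W"`, `"P"`, `NA_character_`.
#' @export
decode_classes <- function(raw, threshold = 0.5) {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == 2)
  top <- pmax(raw[1, ], raw[2, ])
  cls <- ifelse(top < threshold | raw[1, ] == raw[2, ], NA_character_,
                ifelse(raw[1, ] > raw[2, ], "W", "P"))
  cls
}

#' Detect perturbations by the consecutive-P rule
#'
#' A potential perturbation is detected when `run_length` consecutive
#' samples are classified `P`; `W` or `NA` samples break a run. One
#' detection is registered per maximal run of at least `run_length` P
#' samples, at the index of the run's `run_length`-th sample.
#'
#' @param classes character vector over `"W"`, `"P"`, `NA`.
#' @param run_length required consecutive P samples (default 5).
#' @return Integer vector of detection indices (1-based), possibly empty.
#' @export
detect_runs <- function(classes, run_length = 5L) {
  stopifnot(run_length >= 1)
  is_p <- !is.na(classes) & classes == "P"
  r <- rle(is_p)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= run_length
  as.integer(starts[hit] + run_length - 1L)
}

#' Label a classified trial's outcome
#'
#' Each classified trial contributes one walking-phase outcome and one
#' perturbation-phase outcome: a detection before `onset_index` makes the
#' WP a false positive (else true negative); a detection at or after
#' `onset_index` makes the PP a true positive (else false negative). A run
#' straddling the boundary is assigned by the index of its
#' `run_length`-th sample. For a TP, the detection time counts from the
#' onset through the detection sample:
#' `DT = (index - onset_index + 1) / fs`.
#'
#' @param detections integer detection indices from [detect_runs()].
#' @param onset_index index of the first post-onset sample.
#' @param fs sampling frequency, Hz.
#' @return Object of class `detection_outcome`: `wp_outcome` (`"TN"`/
#'   `"FP"`), `pp_outcome` (`"TP"`/`"FN"`), `detection_index` and
#'   `detection_time` (s; `NA` unless TP).
#' @export
label_outcome <- function(detections, onset_index, fs) {
  pre <- detections[detections < onset_index]
  post <- detections[detections >= onset_index]
  wp <- if (length(pre)) "FP" else "TN"
  if (length(post)) {
    idx <- min(post)
    structure(list(wp_outcome = wp, pp_outcome = "TP",
                   detection_index = idx,
                   detection_time = (idx - onset_index + 1) / fs),
              class = "detection_outcome")
  } else {
    structure(list(wp_outcome = wp, pp_outcome = "FN",
                   detection_index = NA_integer_,
                   detection_time = NA_real_),
              class = "detection_outcome")
  }
}

#' Classify one trial end to end
#'
#' Convenience wrapper: decode, run the detection rule, label the outcome.
#'
#' @param raw 2 x T network outputs.
#' @param onset_index index of the first post-onset sample.
#' @param fs sampling frequency, Hz.
#' @param threshold activity threshold.
#' @param run_length consecutive-P requirement.
#' @return A `detection_outcome`.
#' @export
classify_trial <- function(raw, onset_index, fs, threshold = 0.5,
                           run_length = 5L) {
  cls <- decode_classes(raw, threshold)
  label_outcome(detect_runs(cls, run_length), onset_index, fs)
}

#' Aggregate detection outcomes into a performance report
#'
#' Counts TP/FP/TN/FN over all outcomes, averages the true positives'
#' detection times into MDT (mean and sd, s) and computes
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)` and the
#' balanced `accuracy = (sensitivity + specificity) / 2`. A metric with a
#' zero denominator is reported as `NA`, never silently 0.
#'
#' @param outcomes list of `detection_outcome` objects.
#' @param by optional data.frame (one row per outcome) of grouping
#'   variables, e.g. perturbation type; a per-group breakdown is attached.
#' @return Object of class `performance_report`.
#' @export
aggregate_outcomes <- function(outcomes, by = NULL) {
  if (length(outcomes) == 0) stop("no outcomes to aggregate")
  pp <- vapply(outcomes, `[[`, "", "pp_outcome")
  wp <- vapply(outcomes, `[[`, "", "wp_outcome")
  dt <- vapply(outcomes, `[[`, 0, "detection_time")
  rep <- performance_from_counts(sum(pp == "TP"), sum(wp == "FP"),
                                 sum(wp == "TN"), sum(pp == "FN"),
                                 dt[pp == "TP"])
  if (!is.null(by)) {
    stopifnot(nrow(by) == length(outcomes))
    key <- interaction(by, drop = TRUE)
    rep$breakdown <- do.call(rbind, lapply(levels(key), function(k) {
      i <- key == k
      sub <- performance_from_counts(sum(pp[i] == "TP"), sum(wp[i] == "FP"),
                                     sum(wp[i] == "TN"), sum(pp[i] == "FN"),
                                     dt[i][pp[i] == "TP"])
      cbind(unique(by[i, , drop = FALSE]), as.data.frame(sub[METRIC_COLS]),
            row.names = NULL)
    }))
  }
  rep
}

METRIC_COLS <- c("tp", "fp", "tn", "fn", "mdt_mean", "mdt_sd",
                 "sensitivity", "specificity", "accuracy")

performance_from_counts <- function(tp, fp, tn, fn, dts = numeric()) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    mdt_mean = if (length(dts)) mean(dts) else NA_real_,
    mdt_sd = if (length(dts) > 1) stats::sd(dts) else NA_real_,
    sensitivity = sens, specificity = spec, accuracy = acc
  ), class = "performance_report")
}

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity fractions or percentages (both on the
#'   same scale).
#' @return `(sensitivity + specificity) / 2`, on the input scale.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("performance_report: TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  if (!is.na(x$mdt_mean)) {
    cat(sprintf("  MDT %.0f +/- %.0f ms\n", 1000 * x$mdt_mean,
                1000 * (x$mdt_sd %||% NA_real_)))
  }
  invisible(x)
}

#' Write a performance report to JSON and CSV
#'
#' @param report a `performance_report`.
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "performance_report"))
  jsonlite::write_json(report[METRIC_COLS], paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report[METRIC_COLS]),
                   paste0(path, ".csv"), row.names = FALSE)
  if (!is.null(report$breakdown)) {
    utils::write.csv(report$breakdown, paste0(path, "_breakdown.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}
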