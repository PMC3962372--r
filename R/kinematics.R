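# Segment CoM kinematics: anthropometric CoM location along the segment
# axis, three-point central differentiation to linear acceleration, and
# assembly of the per-subject data matrix M.

#' Anthropometric CoM ratios (de Leva)
#'
#' Longitudinal centre-of-mass position of each segment as a fraction of
#' segment length from the proximal endpoint, after the de Leva adjustment
#' of the Zatsiorsky tables (male values). Chest and abdomen/pelvis use the
#' upper- and lower-trunk entries; head/neck is measured from the vertex.
#'
#' @return Named numeric vector over the 15 segments, each value in (0, 1).
#' @export
de_leva_ratios <- function() {
  c(HN = 0.5002, T = 0.5066, P = 0.6115,
    LA = 0.5772, RA = 0.5772, LFA = 0.4574, RFA = 0.4574,
    LH = 0.7900, RH = 0.7900, LT = 0.4095, RT = 0.4095,
    LS = 0.4459, RS = 0.4459, LF = 0.4415, RF = 0.4415)
}

#' Segment centre of mass from endpoint trajectories
#'
#' The CoM lies on the line from the proximal to the distal endpoint at a
#' fixed anthropometric fraction of the segment length:
#' `com = proximal + ratio * (distal - proximal)` per axis and sample.
#'
#' @param proximal,distal numeric matrices `[samples x 3]` of endpoint
#'   positions, m.
#' @param ratio CoM position as a fraction of segment length from the
#'   proximal endpoint, in (0, 1) (0 and 1 are accepted as limits).
#' @return Matrix `[samples x 3]` of CoM positions, m.
#' @export
segment_com <- function(proximal, distal, ratio) {
  proximal <- as.matrix(proximal); distal <- as.matrix(distal)
  if (!identical(dim(proximal), dim(distal))) {
    stop("proximal and distal trajectories must have identical dimensions")
  }
  if (length(ratio) != 1 || ratio < 0 || ratio > 1) {
    stop("ratio must be a single value in [0, 1]")
  }
  proximal + ratio * (distal - proximal)
}

#' Acceleration by three-point central differences
#'
#' Second derivative of position: `a[t] = (p[t+1] - 2 p[t] + p[t-1]) * fs^2`
#' at interior samples. The two boundary samples replicate the nearest
#' interior acceleration so the output keeps the input length (and hence
#' stays aligned with per-sample labels).
#'
#' @param pos numeric vector or `[samples x d]` matrix of positions, m.
#' @param fs sampling frequency, Hz.
#' @return Acceleration with the same shape as `pos`, m/s^2.
#' @export
central_diff_accel <- function(pos, fs) {
  if (fs <= 0) stop("fs must be positive")
  vec <- is.null(dim(pos))
  p <- if (vec) matrix(pos, ncol = 1) else as.matrix(pos)
  n <- nrow(p)
  if (n < 3) stop("need at least 3 samples to differentiate")
  a <- matrix(NA_real_, n, ncol(p))
  idx <- 2:(n - 1)
  a[idx, ] <- (p[idx + 1, , drop = FALSE] - 2 * p[idx, , drop = FALSE] +
                 p[idx - 1, , drop = FALSE]) * fs^2
  a[1, ] <- a[2, ]
  a[n, ] <- a[n - 1, ]
  if (vec) drop(a) else a
}

#' Read per-segment endpoint trajectories from CSV
#'
#' Expects columns `<SEG>_prox_x`, `<SEG>_prox_y`, `<SEG>_prox_z`,
#' `<SEG>_dist_x`, ... for each requested segment.
#'
#' @param path CSV path.
#' @param segments segment codes to extract (default all 15).
#' @return Named list per segment with `proximal` and `distal`
#'   `[samples x 3]` matrices.
#' @export
read_endpoints_csv <- function(path, segments = SEGMENTS) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- lapply(segments, function(seg) {
    need <- c(paste0(seg, "_prox_", AXES), paste0(seg, "_dist_", AXES))
    if (!all(need %in% names(df))) {
      stop("missing endpoint columns for segment ", seg)
    }
    list(proximal = as.matrix(df[, need[1:3]]),
         distal = as.matrix(df[, need[4:6]]))
  })
  names(out) <- segments
  out
}

#' CoM accelerations for all segments from endpoint trajectories
#'
#' Applies [segment_com()] with the anthropometric ratio of each segment,
#' then [central_diff_accel()], and stacks the result into the package's
#' channel layout (rows `<SEG>_<axis>`).
#'
#' @param endpoints list as returned by [read_endpoints_csv()].
#' @param fs sampling frequency, Hz.
#' @param ratios named CoM-ratio vector (default [de_leva_ratios()]).
#' @return Matrix `[3*length(endpoints) x samples]` of accelerations.
#' @export
com_accelerations <- function(endpoints, fs, ratios = de_leva_ratios()) {
  segs <- names(endpoints)
  rows <- lapply(segs, function(seg) {
    com <- segment_com(endpoints[[seg]]$proximal, endpoints[[seg]]$distal,
                       ratios[[seg]])
    t(central_diff_accel(com, fs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- channel_names(segs)
  out
}

#' Assemble the per-subject dataset matrix M
#'
#' Column-wise concatenation of the trials' acceleration matrices in trial
#' order, with the label vectors concatenated identically. For the standard
#' 20-trial, 600-sample design M is 45 x 12000.
#'
#' @param trials list of `trial_window` objects with identical channel
#'   layout and sample count.
#' @return Object of class `segment_dataset`: `M` (channels x samples),
#'   `label` (factor), `trial_id` (integer per column), `channel_map`
#'   (segment code per channel), `trials` metadata (ptype/session per trial),
#'   `n_samples` per trial, `onset_index`, `fs`.
#' @export
assemble_dataset <- function(trials) {
  stopifnot(length(trials) >= 1)
  ref <- rownames(trials[[1]]$accel)
  ncols <- ncol(trials[[1]]$accel)
  for (tr in trials) {
    if (!identical(rownames(tr$accel), ref) || ncol(tr$accel) != ncols) {
      stop("all trials must share channel order and sample count")
    }
  }
  M <- do.call(cbind, lapply(trials, `[[`, "accel"))
  label <- factor(unlist(lapply(trials, function(tr) as.character(tr$label))),
                  levels = c("W", "P"))
  structure(list(
    M = M, label = label,
    trial_id = rep(seq_along(trials), each = ncols),
    channel_map = channel_segments(unique(sub("_[xyz]$", "", ref))),
    trials = data.frame(
      ptype = vapply(trials, function(tr) tr$ptype$code, ""),
      session = vapply(trials, function(tr) tr$session, 0L)),
    n_samples = ncols,
    onset_index = trials[[1]]$onset_index,
    fs = trials[[1]]$fs
  ), class = "segment_dataset")
}

#' Split a dataset back into per-trial matrices
#'
#' Inverse of the concatenation in [assemble_dataset()].
#'
#' @param ds a `segment_dataset`.
#' @return List of `[channels x n_samples]` matrices, one per trial.
#' @export
split_dataset <- function(ds) {
  lapply(unique(ds$trial_id), function(i) {
    ds$M[, ds$trial_id == i, drop = FALSE]
  })
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("segment_dataset: %d channels x %d samples (%d trials of %d)\n",
              nrow(x$M), ncol(x$M), nrow(x$trials), x$n_samples))
  invisible(x)
}
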