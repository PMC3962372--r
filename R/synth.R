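# Synthetic gait + slipping-perturbation generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# quasi-periodic walking accelerations in 45 channels (15 segments x 3 axes)
# plus a perturbation-locked damped transient whose amplitude is largest in
# the distal segments, with additive Gaussian sensor noise.

GRAVITY <- 9.81  # m/s^2

#' Walking speed from a Froude number
#'
#' Dynamically similar walking speeds are imposed across subjects by fixing
#' the Froude number Fr = v^2 / (g L): v = sqrt(Fr * g * L) with
#' g = 9.81 m/s^2 and L the leg length.
#'
#' @param leg_length leg length in metres (> 0).
#' @param froude dimensionless Froude number (>= 0); 0.15 is the value used
#'   for the treadmill protocol this package models.
#' @return Walking speed in m/s.
#' @examples
#' froude_speed(0.822, 0.15)  # ~1.10 m/s
#' @export
froude_speed <- function(leg_length, froude = 0.15) {
  if (!is.numeric(leg_length) || any(leg_length <= 0)) {
    stop("leg_length must be positive")
  }
  if (!is.numeric(froude) || any(froude < 0)) {
    stop("froude must be non-negative")
  }
  sqrt(froude * GRAVITY * leg_length)
}

# per-segment walking amplitude on the dominant (x) axis, m/s^2.
# Distal segments move more than proximal ones during gait.
WALK_AMPLITUDE <- c(
  HN = 0.5, T = 0.6, P = 0.8,
  LA = 1.0, RA = 1.0, LFA = 1.5, RFA = 1.5, LH = 2.0, RH = 2.0,
  LT = 1.5, RT = 1.5, LS = 2.5, RS = 2.5, LF = 3.5, RF = 3.5
)

# relative walking amplitude per axis (x antero-posterior, y medio-lateral,
# z vertical)
AXIS_SCALE <- c(x = 1.0, y = 0.6, z = 1.2)

# default dimensionless perturbation gains: distal >> proximal
DEFAULT_GAIN <- c(
  HN = 0.6, T = 0.8, P = 1.0,
  LA = 1.2, RA = 1.2, LFA = 1.8, RFA = 1.8, LH = 4.0, RH = 4.0,
  LT = 1.2, RT = 1.2, LS = 2.0, RS = 2.0, LF = 5.0, RF = 5.0
)

# transient onset delay per segment, s: the mechanical chain propagates the
# belt perturbation from the feet upward
DEFAULT_LATENCY <- c(
  HN = 0.06, T = 0.06, P = 0.06,
  LA = 0.08, RA = 0.08, LFA = 0.08, RFA = 0.08, LH = 0.08, RH = 0.08,
  LT = 0.03, RT = 0.03, LS = 0.03, RS = 0.03, LF = 0.00, RF = 0.00
)

TRANSIENT_BASE_AMP <- 4.0   # m/s^2 per unit gain
TRANSIENT_TAU <- 0.15       # s, damping time constant
TRANSIENT_FREQ <- 3.0       # Hz, transient oscillation frequency

#' Subject parameters for the synthetic generator
#'
#' Bundles everything that defines one synthetic subject: anthropometry
#' (leg length, hence walking speed through the Froude number), cadence,
#' per-channel sensor noise, per-segment perturbation gains and transient
#' latencies, window geometry and the master seed.
#'
#' @param leg_length leg length, m.
#' @param froude dimensionless Froude number fixing the walking speed.
#' @param cadence step frequency, Hz.
#' @param noise_sd Gaussian sensor noise sd per channel, m/s^2.
#' @param perturbation_gain named numeric vector (one entry per segment) of
#'   dimensionless transient amplitude multipliers; all >= 0.
#' @param transient_latency named numeric vector of per-segment transient
#'   onset delays, s.
#' @param fs sampling frequency, Hz.
#' @param pre_s,post_s window extent before/after perturbation onset, s.
#' @param seed master seed; per-trial seeds are derived from it.
#' @return Object of class `subject_params`.
#' @export
subject_params <- function(leg_length = 0.822, froude = 0.15,
                           cadence = 1.8, noise_sd = 0.1,
                           perturbation_gain = DEFAULT_GAIN,
                           transient_latency = DEFAULT_LATENCY,
                           fs = 100, pre_s = 5, post_s = 1, seed = 1L) {
  gain <- perturbation_gain[SEGMENTS]
  lat <- transient_latency[SEGMENTS]
  if (anyNA(gain)) stop("perturbation_gain must name all 15 segments")
  if (anyNA(lat)) stop("transient_latency must name all 15 segments")
  if (any(gain < 0)) stop("perturbation gains must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  speed <- froude_speed(leg_length, froude)
  structure(list(
    leg_length = leg_length, froude = froude, cadence = cadence,
    walking_speed = speed, noise_sd = noise_sd,
    perturbation_gain = gain, transient_latency = lat,
    fs = fs, pre_s = pre_s, post_s = post_s, seed = as.integer(seed)
  ), class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(
    "subject_params: leg %.3f m, speed %.2f m/s (Fr %.2f), cadence %.2f Hz,\n",
    x$leg_length, x$walking_speed, x$froude, x$cadence))
  cat(sprintf("  noise sd %.3f m/s^2, fs %g Hz, window %g+%g s, seed %d\n",
              x$noise_sd, x$fs, x$pre_s, x$post_s, x$seed))
  invisible(x)
}

# evaluate a function with a temporary RNG state, restoring the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# subject-level random phases: one per channel per harmonic, fixed for all
# of the subject's trials so that the gait pattern is consistent
subject_phases <- function(params) {
  with_seed(params$seed, matrix(stats::runif(45 * 2, 0, 2 * pi), nrow = 45))
}

# direction sign pattern on (x, y): longitudinal from N/S, transversal from
# E/W in the code; normalized to unit planar magnitude
direction_pattern <- function(code) {
  sx <- (grepl("N", code) - grepl("S", code))
  sy <- (grepl("E", code) - grepl("W", code))
  n <- sqrt(sx^2 + sy^2)
  c(x = sx / n, y = sy / n, z = 0.5)
}

#' Generate one perturbation trial
#'
#' Builds a labelled trial window of 45-channel CoM accelerations: a
#' quasi-periodic walking component (two harmonics at the cadence and twice
#' the cadence, segment-specific amplitudes, subject-specific phases), a
#' perturbation-locked exponentially damped sinusoid starting at the onset
#' plus the segment's transient latency (amplitude proportional to the
#' segment's gain, sign pattern set by the perturbation direction, perturbed
#' side weighted more than the contralateral side), and Gaussian noise.
#'
#' @param params a [subject_params()] object.
#' @param ptype a [perturbation_type()] or a perturbation code string.
#' @param session session index (1 or 2).
#' @param seed trial seed (drives the noise only; gait phases come from the
#'   subject's master seed).
#' @return Object of class `trial_window`: `accel` (45 x 600 matrix, m/s^2,
#'   rows named `<SEG>_<axis>`), `label` (factor, 500 `W` then 100 `P`),
#'   `onset_index` (index of the first post-onset sample), `fs`, `ptype`,
#'   `session`, `seed`.
#' @export
generate_trial <- function(params, ptype, session = 1L, seed = params$seed) {
  stopifnot(inherits(params, "subject_params"))
  if (is.character(ptype)) ptype <- perturbation_type(ptype)
  stopifnot(inherits(ptype, "perturbation_type"))

  fs <- params$fs
  n_pre <- round(params$pre_s * fs)
  n_post <- round(params$post_s * fs)
  n <- n_pre + n_post
  t_all <- (seq_len(n) - 1) / fs     # trial-local time, s
  t_onset <- n_pre / fs              # onset at the first post-onset sample
  onset_index <- n_pre + 1L

  phases <- subject_phases(params)
  seg_of <- channel_segments()
  axis_of <- rep(AXES, times = 15)
  f <- params$cadence

  amp1 <- WALK_AMPLITUDE[seg_of] * AXIS_SCALE[axis_of]
  amp2 <- 0.5 * amp1
  # walking component [45 x n]; per-channel phases recycle down columns
  tm <- matrix(t_all, nrow = 45, ncol = n, byrow = TRUE)
  walk <- amp1 * sin(2 * pi * f * tm + phases[, 1]) +
    amp2 * sin(2 * pi * 2 * f * tm + phases[, 2])

  # perturbation transient
  pat <- direction_pattern(ptype$code)
  side_prefix <- if (ptype$side == "left") "L" else "R"
  side_mult <- ifelse(seg_of %in% MIDLINE_SEGMENTS, 1.0,
                      ifelse(startsWith(seg_of, side_prefix), 1.2, 0.8))
  amp_tr <- TRANSIENT_BASE_AMP * params$perturbation_gain[seg_of] *
    side_mult * pat[axis_of]
  lat <- params$transient_latency[seg_of]
  dt <- outer(lat, t_all, function(l, t) t - t_onset - l)  # 45 x n
  active <- dt >= 0
  transient <- matrix(0, 45, n)
  transient[active] <- exp(-dt[active] / TRANSIENT_TAU) *
    sin(2 * pi * TRANSIENT_FREQ * dt[active])
  transient <- transient * amp_tr

  noise <- with_seed(seed,
                     matrix(stats::rnorm(45 * n, sd = params$noise_sd), 45, n))

  accel <- walk + transient + noise
  rownames(accel) <- channel_names()

  label <- factor(rep(c("W", "P"), c(n_pre, n_post)), levels = c("W", "P"))
  structure(list(accel = accel, label = label, onset_index = onset_index,
                 fs = fs, ptype = ptype, session = as.integer(session),
                 seed = as.integer(seed)),
            class = "trial_window")
}

#' @export
print.trial_window <- function(x, ...) {
  cat(sprintf("trial_window: %s session %d, %d channels x %d samples @ %g Hz, onset at %d\n",
              x$ptype$code, x$session, nrow(x$accel), ncol(x$accel),
              x$fs, x$onset_index))
  invisible(x)
}

#' Generate a subject's full trial set
#'
#' One trial per perturbation type per session: 2 sessions x 10
#' perturbations = 20 trials. Per-trial seeds are derived deterministically
#' from the subject's master seed (XOR with the trial index), so the whole
#' set is reproducible.
#'
#' @param params a [subject_params()] object.
#' @return List of 20 `trial_window` objects (session 1 trials first).
#' @export
generate_subject <- function(params) {
  stopifnot(inherits(params, "subject_params"))
  codes <- perturbation_codes()
  trials <- vector("list", 20L)
  k <- 0L
  for (session in 1:2) {
    for (code in codes) {
      k <- k + 1L
      trials[[k]] <- generate_trial(params, code, session = session,
                                    seed = bitwXor(params$seed, k))
    }
  }
  trials
}

#' Read subject parameters from a YAML or JSON config file
#'
#' Any field of [subject_params()] may appear in the file;
#' `perturbation_gain` and `transient_latency` are maps from segment code
#' to value and may be partial (unlisted segments keep their defaults).
#' The format is chosen by extension (`.yaml`/`.yml` need the yaml
#' package; anything else is parsed as JSON).
#'
#' @param path config file path.
#' @return A `subject_params` object.
#' @export
read_subject_params <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), names(formals(subject_params)))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  for (nm in c("perturbation_gain", "transient_latency")) {
    if (!is.null(cfg[[nm]])) {
      full <- if (nm == "perturbation_gain") DEFAULT_GAIN else DEFAULT_LATENCY
      vals <- unlist(cfg[[nm]])
      full[names(vals)] <- vals
      cfg[[nm]] <- full
    }
  }
  do.call(subject_params, cfg)
}

#' Write a trial to CSV with a JSON sidecar
#'
#' One row per sample with the 45 acceleration columns named
#' `<SEG>_<axis>` plus a `label` column; trial metadata (perturbation code,
#' onset index, sampling rate, session, seed) goes to `<path>.json`.
#'
#' @param trial a `trial_window`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_window"))
  df <- as.data.frame(t(trial$accel))
  df$label <- as.character(trial$label)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(ptype = trial$ptype$code, onset_index = trial$onset_index,
               fs = trial$fs, session = trial$session, seed = trial$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a trial written by [write_trial_csv()]
#'
#' @param path CSV path (its `.json` sidecar must be present).
#' @return A `trial_window`.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  accel <- t(as.matrix(df[, channel_names(), drop = FALSE]))
  structure(list(accel = accel,
                 label = factor(df$label, levels = c("W", "P")),
                 onset_index = as.integer(meta$onset_index), fs = meta$fs,
                 ptype = perturbation_type(meta$ptype),
                 session = as.integer(meta$session),
                 seed = as.integer(meta$seed)),
            class = "trial_window")
}
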