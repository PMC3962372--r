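# Shared fixtures: everything is generated in code at test time.

# a quiet, fast subject for structural tests
quiet_params <- function(seed = 1L, ...) {
  subject_params(seed = seed, noise_sd = 0.05, ...)
}

# cheap nested-LOOCV configuration for structural pipeline tests (small
# network, few epochs, single ICA restart)
cheap_config <- function(seed = 1L, ...) {
  experiment_config(
    train = train_config(hidden_units = 5L, max_epochs = 15L,
                         patience = 5L),
    ica_restarts = 1L, seed = seed, ...)
}

# gains concentrated in the distal extremities, as used for ranking
# recovery checks
extremity_gains <- function(hi = 5, lo = 0.5) {
  g <- stats::setNames(rep(lo, length(SEGMENTS)), SEGMENTS)
  g[c("LF", "RF", "LH", "RH")] <- hi
  g
}

# independent reference for the consecutive-P rule: scan every window of
# `run_length` samples; a full-P window is a detection at its last index
# iff the preceding sample does not extend the run (the run's 5th sample)
brute_force_runs <- function(classes, run_length = 5L) {
  n <- length(classes)
  is_p <- !is.na(classes) & classes == "P"
  hits <- integer()
  for (i in run_length:n) {
    win <- is_p[(i - run_length + 1):i]
    if (all(win)) {
      before <- i - run_length
      if (before == 0 || !is_p[before]) hits <- c(hits, i)
    }
  }
  hits
}

# random W/P/NA class sequence
random_classes <- function(n = 600, p_prob = c(W = 0.55, P = 0.35, `NA` = 0.1)) {
  cls <- sample(c("W", "P", NA_character_), n, replace = TRUE,
                prob = p_prob)
  cls
}

# minimal hand-built ica_model for TSW unit tests
fake_ica_model <- function(A, means = rep(0, nrow(A))) {
  structure(list(W_ICA = t(A), A = A, channel_means = means,
                 n_components = ncol(A), negentropy = NA_real_,
                 converged = TRUE),
            class = "ica_model")
}
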