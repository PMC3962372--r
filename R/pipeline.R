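# Nested leave-one-out experiment: ICA1 ranking once per subject, then for
# each segment combination an outer LOOCV over the 20 trials (ICA2 fitted
# on each 19-trial training set) with an inner LOOCV over the 19 training
# trials for network early stopping. 20 x 19 = 380 classified test-trial
# instances feed one performance report per combination.

#' Experiment configuration
#'
#' @param segment_combinations named list of segment-code vectors; each
#'   must be bilaterally complete (a lateral segment implies its partner).
#'   Default: ALL (15 segments), F (feet), H (hands), FH (feet + hands).
#' @param var_threshold explained-variance fraction for the ICA1 component
#'   count.
#' @param train a [train_config()]; its seed field is ignored (per-fold
#'   seeds derive from `seed`).
#' @param threshold decoding activity threshold.
#' @param run_length consecutive-P detection requirement.
#' @param ica_restarts restarts for each ICA fit.
#' @param seed master seed; fold-level seeds are derived from it.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(segment_combinations = list(
                                ALL = SEGMENTS,
                                F = c("LF", "RF"),
                                H = c("LH", "RH"),
                                FH = c("LH", "RH", "LF", "RF")),
                              var_threshold = 0.95,
                              train = train_config(),
                              threshold = 0.5, run_length = 5L,
                              ica_restarts = 5L, seed = 1L) {
  for (nm in names(segment_combinations)) {
    combo <- segment_combinations[[nm]]
    stopifnot(all(combo %in% SEGMENTS))
    lateral <- setdiff(combo, MIDLINE_SEGMENTS)
    if (!all(CONTRALATERAL[lateral] %in% combo)) {
      stop("combination ", nm, " is not bilaterally complete")
    }
  }
  structure(list(segment_combinations = segment_combinations,
                 var_threshold = var_threshold, train = train,
                 threshold = threshold, run_length = as.integer(run_length),
                 ica_restarts = as.integer(ica_restarts),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' ICA1 stage: rank a subject's segments by informativeness
#'
#' Assembles the full dataset M from all 20 trials, selects the retained
#' component count N by explained variance, fits the ICA and computes the
#' Total Segment Weight ranking.
#'
#' @param trials list of the subject's `trial_window`s.
#' @param cfg an [experiment_config()].
#' @return A `segment_ranking` (its `n_retained` is the N used by the
#'   all-segments ICA2 stage).
#' @export
run_ranking <- function(trials, cfg = experiment_config()) {
  ds <- assemble_dataset(trials)
  N <- select_n_components(ds$M, cfg$var_threshold)
  model <- fit_ica(ds$M, N, seed = cfg$seed, restarts = cfg$ica_restarts,
                   allow_partial = TRUE)
  compute_tsw(model, ds$channel_map)
}

# derived per-fold seeds (kept below 2^31 by construction)
fold_seed <- function(master, i, j = 0L) {
  bitwXor(as.integer(master), as.integer(1000L * i + j))
}

#' One outer LOOCV fold
#'
#' Fits ICA2 on the 19 training trials (restricted to the combination's
#' channels), projects training and test data with the same time-invariant
#' unmixing, then runs the inner LOOCV: for each of the 19 training trials
#' held out as validation set, trains the network on the remaining 18,
#' classifies the projected test trial and scores its outcome. The test
#' trial never enters ICA2 fitting or network training.
#'
#' @param trials the subject's 20 trials.
#' @param i outer fold index (test trial).
#' @param segments segment codes of the combination.
#' @param n_components ICA2 dimensionality (ICA1's N for all segments;
#'   `3 * length(segments)` for reduced subsets).
#' @param cfg an [experiment_config()].
#' @param return_models also return the 19 trained networks (for
#'   structural leakage checks).
#' @return data.frame of 19 outcomes (one per inner fold), with the
#'   trained models attached as an attribute when requested.
#' @export
run_outer_fold <- function(trials, i, segments, n_components, cfg,
                           return_models = FALSE) {
  rows <- channel_indices(segments)
  test <- trials[[i]]
  train_trials <- trials[-i]
  ds <- assemble_dataset(train_trials)
  M_tr <- ds$M[rows, , drop = FALSE]
  ica2 <- fit_ica(M_tr, n_components, seed = fold_seed(cfg$seed, i),
                  restarts = cfg$ica_restarts, allow_partial = TRUE)
  S_tr <- project(ica2, M_tr)
  S_te <- project(ica2, test$accel[rows, , drop = FALSE])
  lab <- ds$label
  tid <- ds$trial_id

  outcomes <- vector("list", length(train_trials))
  models <- if (return_models) vector("list", length(train_trials))
  for (j in seq_along(train_trials)) {
    val <- tid == j
    cfg_j <- cfg$train
    cfg_j$seed <- fold_seed(cfg$seed, i, j)
    net <- train_nn(S_tr[, !val, drop = FALSE], lab[!val],
                    S_tr[, val, drop = FALSE], lab[val], cfg_j)
    out <- classify_trial(nn_forward(net, S_te), test$onset_index,
                          test$fs, cfg$threshold, cfg$run_length)
    outcomes[[j]] <- data.frame(
      outer_trial = i, inner_fold = j, ptype = test$ptype$code,
      session = test$session, wp_outcome = out$wp_outcome,
      pp_outcome = out$pp_outcome, detection_time = out$detection_time,
      stringsAsFactors = FALSE)
    if (return_models) models[[j]] <- net
  }
  res <- do.call(rbind, outcomes)
  if (return_models) attr(res, "models") <- models
  res
}

#' Run the nested LOOCV for one subject and one segment combination
#'
#' @param trials the subject's 20 trials.
#' @param segments segment codes of the combination.
#' @param cfg an [experiment_config()].
#' @param n_components ICA2 dimensionality; by default ICA1's N (via
#'   [run_ranking()]) when all 15 segments are used, else the full subset
#'   dimension `3 * length(segments)` (information reduction has already
#'   been done by choosing the segments).
#' @return A `performance_report` over all 20 x 19 outcomes, with a
#'   per-perturbation-type breakdown and the per-outcome table in
#'   `$outcomes`.
#' @export
run_subject <- function(trials, segments = SEGMENTS,
                        cfg = experiment_config(), n_components = NULL) {
  if (length(trials) != 20) {
    stop("expected 20 trials (2 sessions x 10 perturbations), got ",
         length(trials))
  }
  if (is.null(n_components)) {
    n_components <- if (setequal(segments, SEGMENTS)) {
      run_ranking(trials, cfg)$n_retained
    } else {
      3L * length(segments)
    }
  }
  tabs <- lapply(seq_along(trials), function(i) {
    tryCatch(
      run_outer_fold(trials, i, segments, n_components, cfg),
      error = function(e) stop("outer fold ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  tab <- do.call(rbind, tabs)
  outcomes <- lapply(seq_len(nrow(tab)), function(k) {
    structure(list(wp_outcome = tab$wp_outcome[k],
                   pp_outcome = tab$pp_outcome[k],
                   detection_time = tab$detection_time[k]),
              class = "detection_outcome")
  })
  rep <- aggregate_outcomes(outcomes,
                            by = data.frame(ptype = tab$ptype,
                                            stringsAsFactors = FALSE))
  rep$outcomes <- tab
  rep$n_components <- n_components
  rep$segments <- segments
  rep
}

#' Per-perturbation-type mean detection times for one report
#'
#' One MDT per perturbation type (mean over that type's true-positive
#' detection times), the unit of observation for the statistical
#' comparison.
#'
#' @param report a `performance_report` from [run_subject()].
#' @return data.frame with columns `ptype`, `mdt` (s).
#' @export
mdt_by_type <- function(report) {
  tab <- report$outcomes
  stats::aggregate(detection_time ~ ptype,
                   data = tab[tab$pp_outcome == "TP", ],
                   FUN = mean) |>
    stats::setNames(c("ptype", "mdt"))
}

#' Compare segment combinations statistically
#'
#' For each combination: a two-way main-effects ANOVA of MDT on
#' perturbation direction (5 paired levels) and side (left/right), and for
#' each reduced combination a paired t-test of its MDT against the
#' reference combination, paired by subject x perturbation type.
#'
#' @param mdt long data.frame with columns `combo`, `subject`, `ptype`,
#'   `mdt` (one row per subject x perturbation type x combination).
#' @param reference name of the reference combination (default `"ALL"`).
#' @param alpha significance level for the `significant` flag.
#' @return data.frame, one row per combination: MDT mean/sd (s), ANOVA F
#'   and p for side and direction, paired-t statistic/df/p vs the
#'   reference (`NA` for the reference row), significance flag.
#' @export
compare_combinations <- function(mdt, reference = "ALL", alpha = 0.05) {
  need <- c("combo", "subject", "ptype", "mdt")
  if (!all(need %in% names(mdt))) {
    stop("mdt must have columns ", paste(need, collapse = ", "))
  }
  if (!reference %in% mdt$combo) {
    stop("reference combination ", reference, " not present")
  }
  combos <- unique(mdt$combo)
  cells <- expand.grid(combo = combos, subject = unique(mdt$subject),
                       ptype = unique(mdt$ptype), stringsAsFactors = FALSE)
  have <- paste(mdt$combo, mdt$subject, mdt$ptype)
  missing <- cells[!paste(cells$combo, cells$subject, cells$ptype) %in% have, ]
  if (nrow(missing) > 0) {
    stop("missing MDT cells: ",
         paste(sprintf("%s/%s/%s", missing$combo, missing$subject,
                       missing$ptype), collapse = "; "))
  }
  info <- PERTURBATION_TABLE[match(mdt$ptype, PERTURBATION_TABLE$code), ]
  mdt$direction <- factor(info$direction)
  mdt$side <- factor(info$side)
  key <- function(d) paste(d$subject, d$ptype)
  ref <- mdt[mdt$combo == reference, ]

  rows <- lapply(c(reference, setdiff(combos, reference)), function(cb) {
    sub <- mdt[mdt$combo == cb, ]
    an <- summary(stats::aov(mdt ~ direction + side, data = sub))[[1]]
    out <- data.frame(
      combo = cb,
      mdt_mean = mean(sub$mdt), mdt_sd = stats::sd(sub$mdt),
      F_direction = an["direction", "F value"],
      p_direction = an["direction", "Pr(>F)"],
      F_side = an["side", "F value"],
      p_side = an["side", "Pr(>F)"],
      t_stat = NA_real_, t_df = NA_real_, p_ttest = NA_real_,
      stringsAsFactors = FALSE)
    if (cb != reference) {
      d <- sub$mdt[match(key(ref), key(sub))] - ref$mdt
      if (stats::sd(d) == 0) {  # degenerate paired test, reported explicitly
        out$t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        out$t_df <- length(d) - 1
        out$p_ttest <- if (mean(d) == 0) 1 else 0
      } else {
        tt <- stats::t.test(sub$mdt[match(key(ref), key(sub))], ref$mdt,
                            paired = TRUE)
        out$t_stat <- unname(tt$statistic)
        out$t_df <- unname(tt$parameter)
        out$p_ttest <- tt$p.value
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  res$significant <- !is.na(res$p_ttest) & res$p_ttest < alpha
  res
}

#' Run the full experiment for a set of synthetic subjects
#'
#' Generates each subject, runs the nested LOOCV for every configured
#' segment combination and collects the per-type MDT table for
#' [compare_combinations()].
#'
#' @param subject_seeds integer vector of master seeds, one per subject.
#' @param cfg an [experiment_config()].
#' @param params_fn function(seed) returning a [subject_params()]; defaults
#'   to the generator defaults with that seed.
#' @return List: `reports` (nested list subject -> combination),
#'   `mdt` (long data.frame for the comparison).
#' @export
run_experiment <- function(subject_seeds, cfg = experiment_config(),
                           params_fn = function(seed) subject_params(seed = seed)) {
  reports <- list()
  mdt_rows <- list()
  for (s in seq_along(subject_seeds)) {
    trials <- generate_subject(params_fn(subject_seeds[s]))
    cfg_s <- cfg
    cfg_s$seed <- as.integer(subject_seeds[s])
    reports[[s]] <- lapply(cfg$segment_combinations, function(segs) {
      run_subject(trials, segs, cfg_s)
    })
    for (nm in names(cfg$segment_combinations)) {
      m <- mdt_by_type(reports[[s]][[nm]])
      mdt_rows[[length(mdt_rows) + 1L]] <-
        cbind(combo = nm, subject = s, m, stringsAsFactors = FALSE)
    }
  }
  list(reports = reports,
       mdt = do.call(rbind, mdt_rows))
}
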