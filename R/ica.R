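# Independent component analysis of the channel x sample acceleration
# matrix: PCA-based choice of the retained dimensionality, FastICA-style
# fixed-point estimation with a tanh contrast and deflation, projection
# into component space, and the Total Segment Weight (TSW) informativeness
# ranking with bilateral subset selection.

# E[log cosh(x)] for x ~ N(0,1), the Gaussian baseline of the negentropy
# proxy (computed once by quadrature to double precision)
LOGCOSH_GAUSS <- 0.3745672074914380

# eigen decomposition of the channel covariance of a centred matrix
channel_eigen <- function(Xc) {
  C <- Xc %*% t(Xc) / (ncol(Xc) - 1)
  e <- eigen(C, symmetric = TRUE)
  e$values[e$values < 0] <- 0
  e
}

#' Choose the number of retained independent components
#'
#' N is the smallest number of principal components of the mean-centred
#' data that explains at least `var_threshold` of the total variance,
#' capped at the numerical rank of the matrix.
#'
#' @param M data matrix, channels x samples.
#' @param var_threshold fraction of variance to retain, in (0, 1].
#' @return Integer N, `1 <= N <= nrow(M)`.
#' @export
select_n_components <- function(M, var_threshold = 0.95) {
  if (var_threshold <= 0 || var_threshold > 1) {
    stop("var_threshold must be in (0, 1]")
  }
  Xc <- M - rowMeans(M)
  ev <- channel_eigen(Xc)$values
  rank <- sum(ev > max(ev) * 1e-12)
  cumfrac <- cumsum(ev) / sum(ev)
  N <- which(cumfrac >= var_threshold - 1e-12)[1]
  as.integer(min(max(N, 1L), rank))
}

#' Fit an ICA model by tanh-contrast fixed-point iteration
#'
#' Whitens the mean-centred data to `n_components` dimensions by PCA, then
#' extracts components one at a time (deflation) with the FastICA
#' fixed-point update under the log-cosh contrast. Several restarts from
#' different seeded initial vectors are run and the solution with the
#' largest negentropy proxy is kept, which makes the fit deterministic
#' given `seed`.
#'
#' @param M data matrix, channels x samples (centred internally).
#' @param n_components number of components N (<= numerical rank of M).
#' @param seed integer seed for the restart initializations.
#' @param restarts number of random restarts (default 5).
#' @param maxit fixed-point iteration cap per component.
#' @param tol convergence tolerance on the direction change.
#' @param allow_partial if no restart converges fully, keep the best
#'   partially converged rotation with a warning instead of erroring
#'   (used by the pipeline, where full-dimension fits may contain
#'   contrast-free noise directions).
#' @return Object of class `ica_model`: `W_ICA` (N x C unmixing applied to
#'   centred channels), `A` (C x N mixing, the pseudo-inverse of `W_ICA`),
#'   `channel_means`, `n_components`, `negentropy`, `converged`, and the
#'   whitening eigensystem.
#' @export
fit_ica <- function(M, n_components, seed = 1L, restarts = 5L,
                    maxit = 500L, tol = 1e-6, allow_partial = FALSE) {
  C <- nrow(M); Tn <- ncol(M)
  means <- rowMeans(M)
  Xc <- M - means
  e <- channel_eigen(Xc)
  rank <- sum(e$values > max(e$values) * 1e-12)
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds the matrix rank (",
         rank, ")")
  }
  N <- as.integer(n_components)
  ev <- e$values[1:N]
  E <- e$vectors[, 1:N, drop = FALSE]
  K <- diag(1 / sqrt(ev), N) %*% t(E)      # whitening, N x C
  Z <- K %*% Xc                             # N x Tn, unit covariance

  best <- NULL
  best_partial <- NULL
  diag_msgs <- character()
  for (r in seq_len(restarts)) {
    W0 <- with_seed(as.integer(seed) + r - 1L,
                    matrix(stats::rnorm(N * N), N, N))
    fit <- ica_deflate(Z, W0, maxit, tol)
    if (!fit$converged) {
      diag_msgs <- c(diag_msgs, sprintf(
        "restart %d: component(s) %s not converged in %d iterations",
        r, paste(fit$failed, collapse = ","), maxit))
      if (is.null(best_partial) ||
          length(fit$failed) < length(best_partial$failed) ||
          (length(fit$failed) == length(best_partial$failed) &&
             fit$negentropy > best_partial$negentropy)) {
        best_partial <- fit
      }
      next
    }
    if (is.null(best) || fit$negentropy > best$negentropy) best <- fit
  }
  if (is.null(best)) {
    # full-dimension fits can leave a near-Gaussian (noise) direction
    # oscillating between fixed points; such directions carry no contrast
    # and the best partial solution is still a valid orthonormal rotation
    if (allow_partial) {
      warning("ICA kept a partially converged solution: ",
              diag_msgs[[1]], call. = FALSE)
      best <- best_partial
    } else {
      stop("ICA failed to converge in all restarts:\n  ",
           paste(diag_msgs, collapse = "\n  "))
    }
  }
  W_ICA <- best$W %*% K                      # N x C
  A <- E %*% diag(sqrt(ev), N) %*% t(best$W) # C x N, right inverse of W_ICA
  structure(list(W_ICA = W_ICA, A = A, channel_means = means,
                 n_components = N, negentropy = best$negentropy,
                 converged = best$converged, eigenvalues = e$values,
                 whitening = K, seed = as.integer(seed)),
            class = "ica_model")
}

# deflation loop on whitened data Z (N x T); W0 holds initial row vectors
ica_deflate <- function(Z, W0, maxit, tol) {
  N <- nrow(Z); Tn <- ncol(Z)
  W <- matrix(0, N, N)
  failed <- integer()
  for (i in seq_len(N)) {
    w <- W0[i, ]
    if (i > 1) {  # start orthogonal to the components already found
      Wp <- W[seq_len(i - 1), , drop = FALSE]
      w <- w - as.vector(t(Wp) %*% (Wp %*% w))
    }
    w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(maxit)) {
      u <- as.vector(w %*% Z)
      g <- tanh(u)
      gp <- 1 - g^2
      w_new <- as.vector(Z %*% g) / Tn - mean(gp) * w
      if (i > 1) {
        Wp <- W[seq_len(i - 1), , drop = FALSE]
        w_new <- w_new - as.vector(t(Wp) %*% (Wp %*% w_new))
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      if (abs(abs(sum(w_new * w)) - 1) < tol) {
        w <- w_new
        ok <- TRUE
        break
      }
      w <- w_new
    }
    if (!ok) failed <- c(failed, i)
    W[i, ] <- w
  }
  S <- W %*% Z
  negent <- sum((rowMeans(log(cosh(S))) - LOGCOSH_GAUSS)^2)
  list(W = W, converged = length(failed) == 0, failed = failed,
       negentropy = negent)
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("ica_model: %d components over %d channels (negentropy proxy %.4g)\n",
              x$n_components, length(x$channel_means), x$negentropy))
  invisible(x)
}

#' Project data into the component space of a fitted ICA model
#'
#' `S = W_ICA %*% (X - channel_means)`. Applied to the training matrix this
#' returns the training components (unit variance by construction); applied
#' to held-out data it uses the time-invariant unmixing unchanged.
#'
#' @param model an `ica_model`.
#' @param X matrix with the same channel count the model was fitted on.
#' @return Component matrix, `n_components` x samples.
#' @export
project <- function(model, X) {
  stopifnot(inherits(model, "ica_model"))
  if (nrow(X) != length(model$channel_means)) {
    stop("X has ", nrow(X), " channels; model expects ",
         length(model$channel_means))
  }
  model$W_ICA %*% (X - model$channel_means)
}

#' Total Segment Weight ranking
#'
#' The informativeness of a body segment is its cumulative absolute loading
#' on the retained independent components: each mixing-matrix column is
#' normalized to unit norm (so no component dominates by scale), the
#' absolute weights of the segment's three channels are summed over all
#' components, and the totals are normalized to percentages. TSW is
#' invariant to the ICA permutation/sign indeterminacies.
#'
#' @param model an `ica_model`.
#' @param channel_map character vector assigning each channel to a segment
#'   code (default the full 45-channel layout).
#' @return Object of class `segment_ranking`: `tsw` (named percentages,
#'   canonical segment order), `rank` (segment codes, descending TSW, ties
#'   broken by canonical order), `n_retained`.
#' @export
compute_tsw <- function(model, channel_map = channel_segments()) {
  stopifnot(inherits(model, "ica_model"))
  A <- model$A
  if (length(channel_map) != nrow(A)) {
    stop("channel_map length must equal the model's channel count")
  }
  if (!all(channel_map %in% SEGMENTS)) {
    stop("channel_map contains unknown segment codes")
  }
  colnorm <- sqrt(colSums(A^2))
  An <- sweep(abs(A), 2, colnorm, "/")
  segs <- SEGMENTS[SEGMENTS %in% channel_map]
  raw <- vapply(segs, function(s) sum(An[channel_map == s, ]), 0)
  tsw <- 100 * raw / sum(raw)
  ord <- order(-tsw, match(segs, SEGMENTS))
  structure(list(tsw = tsw, rank = segs[ord],
                 n_retained = model$n_components),
            class = "segment_ranking")
}

#' @export
print.segment_ranking <- function(x, ...) {
  cat(sprintf("segment_ranking (%d ICs retained):\n", x$n_retained))
  for (s in x$rank) cat(sprintf("  %-4s %6.2f %%\n", s, x$tsw[[s]]))
  invisible(x)
}

#' Select the top-ranked bilateral segment subset
#'
#' Walks the ranking from the top; whenever a lateral segment is taken its
#' contralateral partner is included with it (the perturbed side is unknown
#' in advance), while midline segments count as single entries. Stops after
#' `k_pairs` groups.
#'
#' @param ranking a `segment_ranking`.
#' @param k_pairs number of ranked groups (bilateral pairs or midline
#'   singletons) to take.
#' @return Character vector of segment codes in canonical order.
#' @export
select_bilateral_subset <- function(ranking, k_pairs) {
  stopifnot(inherits(ranking, "segment_ranking"), k_pairs >= 1)
  chosen <- character()
  groups <- 0L
  for (seg in ranking$rank) {
    if (seg %in% chosen) next
    group <- if (seg %in% MIDLINE_SEGMENTS) seg else
      c(seg, CONTRALATERAL[[seg]])
    chosen <- c(chosen, group)
    groups <- groups + 1L
    if (groups >= k_pairs) break
  }
  SEGMENTS[SEGMENTS %in% chosen]
}

#' Write a segment ranking to JSON and CSV
#'
#' @param ranking a `segment_ranking`.
#' @param path output path without extension; `<path>.json` and
#'   `<path>.csv` are written.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "segment_ranking"))
  jsonlite::write_json(
    list(tsw = as.list(ranking$tsw), rank = ranking$rank,
         n_retained = ranking$n_retained),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(segment = names(ranking$tsw), tsw_percent = ranking$tsw,
               rank = match(names(ranking$tsw), ranking$rank)),
    paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
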