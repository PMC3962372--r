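# super-Gaussian (Laplace) sources for recovery tests
laplace_sources <- function(k, n) {
  matrix(stats::rexp(k * n) * sample(c(-1, 1), k * n, replace = TRUE),
         k, n) / sqrt(2)
}

# best-permutation mean absolute correlation between recovered and true
# sources (greedy assignment on |cor|)
match_abs_cor <- function(S_hat, S_true) {
  cm <- abs(stats::cor(t(S_hat), t(S_true)))
  picks <- numeric(nrow(S_true))
  for (k in seq_len(nrow(S_true))) {
    i <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    picks[k] <- cm[i[1], i[2]]
    cm[i[1], ] <- -1; cm[, i[2]] <- -1
  }
  picks
}

test_that("component count selection matches the eigen-spectrum", {
  # one nonzero channel -> rank 1
  M <- matrix(0, 4, 200)
  M[2, ] <- rnorm(200)
  expect_equal(select_n_components(M, 0.5), 1L)
  expect_equal(select_n_components(M, 1.0), 1L)  # capped at rank
  # full-rank data at threshold 1 -> all channels
  set.seed(30)
  Mf <- matrix(rnorm(5 * 500), 5, 500)
  expect_equal(select_n_components(Mf, 1.0), 5L)
  # 3 independent unit-variance sources mixed into 6 channels -> N = 3
  set.seed(31)
  A <- qr.Q(qr(matrix(rnorm(18), 6, 3)))   # balanced (orthonormal) mixing
  M3 <- A %*% laplace_sources(3, 4000)
  expect_equal(select_n_components(M3, 0.95), 3L)
  expect_error(select_n_components(Mf, 0), "var_threshold")
})

test_that("ICA recovers independent super-Gaussian sources", {
  set.seed(40)
  S <- laplace_sources(2, 4000)
  A <- matrix(rnorm(4), 2, 2)
  M <- A %*% S
  fit <- fit_ica(M, 2, seed = 1)
  rec <- project(fit, M)
  expect_true(all(match_abs_cor(rec, S) > 0.95))
})

test_that("ICA is a fixed point on already-independent channels", {
  set.seed(41)
  M <- laplace_sources(3, 6000) * 2 + 1   # scale/offset are absorbed
  fit <- fit_ica(M, 3, seed = 2)
  # mixing is identity up to permutation, sign and channel scale:
  # each column of A loads a single channel
  An <- abs(fit$A) / apply(abs(fit$A), 2, max)
  expect_true(all(colSums(An > 0.2) == 1))
})

test_that("ICA is deterministic given its seed", {
  set.seed(42)
  M <- matrix(rnorm(12), 4, 3) %*% laplace_sources(3, 3000)
  a <- fit_ica(M, 3, seed = 7)
  b <- fit_ica(M, 3, seed = 7)
  expect_identical(a$W_ICA, b$W_ICA)
})

test_that("fit_ica refuses more components than the rank", {
  M <- matrix(0, 5, 300)
  M[1, ] <- rnorm(300); M[2, ] <- 2 * M[1, ]
  expect_error(fit_ica(M, 3), "rank")
})

test_that("projection is exact on training data and errors on mismatch", {
  set.seed(43)
  M <- qr.Q(qr(matrix(rnorm(24), 6, 4))) %*% laplace_sources(4, 5000)
  fit <- fit_ica(M, 4, seed = 3)
  S <- project(fit, M)
  # unit variance by whitening
  expect_equal(unname(apply(S, 1, stats::var)), rep(1, 4), tolerance = 1e-6)
  # projecting the channel means gives the zero matrix
  Z <- project(fit, matrix(fit$channel_means, 6, 10))
  expect_equal(Z, matrix(0, 4, 10), ignore_attr = TRUE)
  expect_error(project(fit, matrix(0, 5, 10)), "channels")
})

test_that("rank-N reconstruction through A matches the PCA truncation bound", {
  set.seed(44)
  # 3 strong super-Gaussian sources plus weak full-rank channel noise
  M <- matrix(rnorm(24), 8, 3) %*% (3 * laplace_sources(3, 4000)) +
    0.1 * laplace_sources(8, 4000)
  fit <- fit_ica(M, 3, seed = 4)
  Xc <- M - rowMeans(M)
  recon <- fit$A %*% project(fit, M)
  resid_ica <- sum((Xc - recon)^2)
  # PCA truncation residual: energy of the dropped eigenvalues
  ev <- eigen(Xc %*% t(Xc) / (ncol(M) - 1), symmetric = TRUE)$values
  resid_pca <- sum(ev[4:8]) * (ncol(M) - 1)
  expect_equal(resid_ica, resid_pca, tolerance = 1e-6)
})

test_that("TSW concentrates on the supporting channels and sums to 100", {
  # mixing supported only on LF/RF channels
  A <- matrix(0, 45, 2)
  rownames(A) <- channel_names()
  A[channel_names("LF"), 1] <- c(1, -2, 0.5)
  A[channel_names("RF"), 2] <- c(0.3, 1.1, -0.7)
  rk <- compute_tsw(fake_ica_model(A))
  expect_equal(rk$tsw[["LF"]] + rk$tsw[["RF"]], 100)
  expect_equal(sum(rk$tsw), 100, tolerance = 1e-9)
  expect_true(all(rk$tsw[setdiff(SEGMENTS, c("LF", "RF"))] == 0))

  # all-equal |A| spreads the weight uniformly
  Au <- matrix(1, 45, 3)
  rku <- compute_tsw(fake_ica_model(Au))
  expect_equal(unname(rku$tsw), rep(100 / 15, 15), tolerance = 1e-12)
  # uniform ties break by canonical segment order
  expect_equal(rku$rank, SEGMENTS)
})

test_that("TSW equals a brute-force accumulation over (IC, channel) pairs", {
  set.seed(50)
  A <- matrix(rnorm(45 * 5), 45, 5)
  rk <- compute_tsw(fake_ica_model(A))
  An <- sweep(abs(A), 2, sqrt(colSums(A^2)), "/")
  seg <- channel_segments()
  raw <- stats::setNames(rep(0, 15), SEGMENTS)
  for (i in 1:5) for (c in 1:45) raw[seg[c]] <- raw[seg[c]] + An[c, i]
  expect_equal(rk$tsw, 100 * raw / sum(raw), tolerance = 1e-12)
})

test_that("TSW is invariant to IC permutation and sign flips", {
  set.seed(51)
  A <- matrix(rnorm(45 * 4), 45, 4)
  perm <- c(3, 1, 4, 2)
  flip <- diag(c(-1, 1, -1, 1))
  rk1 <- compute_tsw(fake_ica_model(A))
  rk2 <- compute_tsw(fake_ica_model(A[, perm] %*% flip))
  expect_identical(rk1$tsw, rk2$tsw)
})

test_that("bilateral subset selection completes pairs and keeps midline single", {
  mk_rank <- function(order) {
    tsw <- stats::setNames(seq(100, 100 - 14 * 2, by = -2), order)
    tsw <- 100 * tsw / sum(tsw)
    structure(list(tsw = tsw[SEGMENTS], rank = order, n_retained = 5L),
              class = "segment_ranking")
  }
  r1 <- mk_rank(c("LF", "RH", setdiff(SEGMENTS, c("LF", "RH"))))
  expect_setequal(select_bilateral_subset(r1, 2), c("LF", "RF", "LH", "RH"))
  r2 <- mk_rank(c("P", setdiff(SEGMENTS, "P")))
  expect_equal(select_bilateral_subset(r2, 1), "P")
  expect_setequal(select_bilateral_subset(r1, 9), SEGMENTS)
})

test_that("ranking report writer emits JSON and CSV", {
  A <- matrix(abs(rnorm(45 * 3)), 45, 3)
  rk <- compute_tsw(fake_ica_model(A))
  path <- file.path(withr::local_tempdir(), "ranking")
  write_ranking(rk, path)
  js <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(js$rank, rk$rank)
  csv <- utils::read.csv(paste0(path, ".csv"))
  expect_equal(nrow(csv), 15)
})
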