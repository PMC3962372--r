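# reference forward/backward pass in plain R, used to cross-check the
# compiled trainer against the exported rprop_step rule
r_backprop <- function(W_h, b_h, W_o, b_o, S, Y) {
  H <- tanh(W_h %*% S + b_h)
  O <- tanh(W_o %*% H + b_o)
  dO <- 2 * (O - Y) * (1 - O^2) / length(Y)
  dH <- (t(W_o) %*% dO) * (1 - H^2)
  list(gW_o = dO %*% t(H), gb_o = rowSums(dO),
       gW_h = dH %*% t(S), gb_h = rowSums(dH),
       mse = mean((O - Y)^2))
}

# a small linearly separable two-class component stream
toy_set <- function(n = 120, seed = 1) {
  set.seed(seed)
  x <- cbind(matrix(rnorm(n, -2, 0.5), 2, n / 2),
             matrix(rnorm(n, 2, 0.5), 2, n / 2))
  lab <- rep(c("W", "P"), each = n / 2)
  list(S = x, label = lab)
}

test_that("forward pass matches the closed form and stays in (-1,1)", {
  m <- nn_init(3, hidden_units = 4, seed = 1)
  z <- structure(list(W_h = matrix(0, 4, 3), b_h = rep(0, 4),
                      W_o = matrix(0, 2, 4), b_o = rep(0, 2)),
                 class = "nn_model")
  expect_equal(nn_forward(z, matrix(rnorm(9), 3)), matrix(0, 2, 3))

  # single hidden unit, hand computation
  h1 <- structure(list(W_h = matrix(0.7, 1, 1), b_h = 0.1,
                       W_o = matrix(c(-1.2, 0.9), 2, 1), b_o = c(0.05, -0.3)),
                  class = "nn_model")
  x <- 0.4
  hid <- tanh(0.7 * x + 0.1)
  expect_equal(nn_forward(h1, matrix(x, 1, 1)),
               matrix(tanh(c(-1.2 * hid + 0.05, 0.9 * hid - 0.3)), 2, 1))

  out <- nn_forward(m, matrix(rnorm(300) * 50, 3))
  expect_true(all(out > -1 & out < 1))
  expect_error(nn_forward(m, matrix(0, 2, 5)), "dimension")
})

test_that("rprop step sizes grow geometrically and shrink on sign flips", {
  w <- 0; st <- NULL
  deltas <- numeric(10)
  for (k in 1:10) {
    up <- rprop_step(w, grad = 1, state = st)
    w <- up$w; st <- up$state
    deltas[k] <- st$delta
  }
  # first step keeps delta0 (no gradient memory yet), then geometric growth
  expect_equal(deltas, pmin(0.07 * 1.2^(0:9), 50), tolerance = 1e-12)

  # alternating gradient: delta halves at every flip
  w <- 0; st <- NULL
  up <- rprop_step(w, 1, st); st <- up$state; d1 <- st$delta
  up <- rprop_step(up$w, -1, st); st <- up$state
  expect_equal(st$delta, d1 * 0.5)
  # memory zeroed after the flip: next same-sign step does not grow
  up <- rprop_step(up$w, -1, st)
  expect_equal(up$state$delta, d1 * 0.5)
})

test_that("rprop converges into the minimizer's bracket on a 1-D quadratic", {
  loss_grad <- function(w) 2 * (w - 3)
  w <- -10; st <- NULL
  for (k in 1:200) {
    up <- rprop_step(w, loss_grad(w), st)
    w <- up$w; st <- up$state
  }
  expect_lt(abs(w - 3), max(st$delta, 1e-3) + 1e-9)
})

test_that("training separates a linearly separable toy set", {
  toy <- toy_set()
  cfg <- train_config(hidden_units = 4, max_epochs = 200, seed = 5)
  net <- train_nn(toy$S, toy$label, toy$S, toy$label, cfg)
  out <- nn_forward(net, toy$S)
  pred <- ifelse(out[1, ] > out[2, ], "W", "P")
  expect_equal(mean(pred == toy$label), 1)
  log <- attr(net, "log")
  # with validation = training set the checkpoint is the last improving epoch
  expect_equal(log$best_val_mse, min(log$val_mse))
  expect_equal(log$best_epoch, which.min(log$val_mse))
})

test_that("training is deterministic and batch-order invariant", {
  toy <- toy_set(seed = 2)
  cfg <- train_config(hidden_units = 4, max_epochs = 50, seed = 9)
  a <- train_nn(toy$S, toy$label, toy$S, toy$label, cfg)
  b <- train_nn(toy$S, toy$label, toy$S, toy$label, cfg)
  expect_identical(a$W_h, b$W_h)
  expect_identical(attr(a, "log")$val_mse, attr(b, "log")$val_mse)

  set.seed(10)
  perm <- sample(ncol(toy$S))
  p <- train_nn(toy$S[, perm], toy$label[perm], toy$S, toy$label, cfg)
  expect_equal(p$W_h, a$W_h, tolerance = 1e-8)
  expect_equal(p$W_o, a$W_o, tolerance = 1e-8)
})

test_that("training loss trends downward on the toy fixture", {
  toy <- toy_set(seed = 3)
  cfg <- train_config(hidden_units = 4, max_epochs = 120,
                      patience = 120, seed = 1)
  net <- train_nn(toy$S, toy$label, toy$S, toy$label, cfg)
  tr <- attr(net, "log")$train_mse
  # Rprop is not strictly monotone; require >= 95 % non-increasing epochs
  expect_gte(mean(diff(tr) <= 1e-12), 0.95)
})

test_that("the compiled trainer applies the exported rprop_step rule", {
  toy <- toy_set(seed = 4)
  Y <- encode_targets(toy$label)
  init <- nn_init(2, hidden_units = 3, seed = 11)
  # two epochs through the compiled path
  fit <- fallseg:::rprop_train_cpp(init$W_h, init$b_h, init$W_o, init$b_o,
                                   toy$S, Y, toy$S, Y,
                                   2L, 10L, 1.2, 0.5, 0.07, 50, 1e-6)
  # replicate in R: gradient + rprop_step per weight block
  W_h <- init$W_h; b_h <- init$b_h; W_o <- init$W_o; b_o <- init$b_o
  st <- list(W_h = NULL, b_h = NULL, W_o = NULL, b_o = NULL)
  for (e in 1:2) {
    g <- r_backprop(W_h, b_h, W_o, b_o, toy$S, Y)
    u <- rprop_step(W_h, g$gW_h, st$W_h); W_h <- u$w; st$W_h <- u$state
    u <- rprop_step(b_h, g$gb_h, st$b_h); b_h <- u$w; st$b_h <- u$state
    u <- rprop_step(W_o, g$gW_o, st$W_o); W_o <- u$w; st$W_o <- u$state
    u <- rprop_step(b_o, g$gb_o, st$b_o); b_o <- u$w; st$b_o <- u$state
  }
  # epoch 2 improves validation in this fixture, so the checkpoint is epoch 2
  expect_equal(fit$best_epoch, 2)
  expect_equal(fit$W_h, W_h, tolerance = 1e-12)
  expect_equal(as.vector(fit$b_h), b_h, tolerance = 1e-12)
  expect_equal(fit$W_o, W_o, tolerance = 1e-12)
  expect_equal(as.vector(fit$b_o), b_o, tolerance = 1e-12)
})

test_that("early stopping halts after patience and keeps the best weights", {
  toy <- toy_set(seed = 6)
  # adversarial validation: constant targets unrelated to training
  val_S <- matrix(rnorm(20), 2, 10)
  cfg <- train_config(hidden_units = 4, max_epochs = 400, patience = 10,
                      seed = 2)
  net <- train_nn(toy$S, toy$label, val_S, rep("W", 10), cfg)
  log <- attr(net, "log")
  expect_lt(log$epochs_run, 400)
  expect_equal(log$epochs_run - log$best_epoch, 10)
  expect_equal(log$best_val_mse, min(log$val_mse))
})

test_that("model JSON serialization round-trips", {
  toy <- toy_set(seed = 7)
  net <- train_nn(toy$S, toy$label, toy$S, toy$label,
                  train_config(hidden_units = 3, max_epochs = 20, seed = 3))
  path <- file.path(withr::local_tempdir(), "net.json")
  write_nn_json(net, path)
  back <- read_nn_json(path)
  expect_equal(back$W_h, net$W_h)
  expect_equal(back$b_o, net$b_o)
  expect_equal(nn_forward(back, toy$S), nn_forward(net, toy$S))
})

test_that("degenerate inputs are refused", {
  expect_error(train_config(eta_plus = 0.9), "eta_plus")
  toy <- toy_set(seed = 8)
  expect_error(train_nn(toy$S[, 0], character(), toy$S, toy$label),
               "non-empty")
  expect_error(encode_targets(c("W", "X")), "labels")
})
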