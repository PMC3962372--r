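# Three-layer feedforward network (tanh hidden and output layers) trained
# by full-batch resilient backpropagation with early stopping on a
# held-out validation trial. Two output units encode the walking (W) and
# perturbation (P) classes with +/-1 one-hot targets, which makes the 0.5
# activity threshold and the three-way W/P/NA decoding downstream natural.

#' Training configuration for the classifier network
#'
#' @param hidden_units hidden layer size (default 80).
#' @param max_epochs epoch cap for Rprop training.
#' @param patience epochs without validation improvement before stopping.
#' @param eta_plus,eta_minus Rprop step growth/shrink factors
#'   (`eta_plus > 1 > eta_minus > 0`).
#' @param delta0 initial per-weight step size.
#' @param delta_max,delta_min step size bounds.
#' @param seed seed for the weight initialization.
#' @return Object of class `train_config`.
#' @export
train_config <- function(hidden_units = 80L, max_epochs = 500L,
                         patience = 25L, eta_plus = 1.2, eta_minus = 0.5,
                         delta0 = 0.07, delta_max = 50, delta_min = 1e-6,
                         seed = 1L) {
  if (!(eta_plus > 1 && 1 > eta_minus && eta_minus > 0)) {
    stop("require eta_plus > 1 > eta_minus > 0")
  }
  structure(list(hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 eta_plus = eta_plus, eta_minus = eta_minus,
                 delta0 = delta0, delta_max = delta_max,
                 delta_min = delta_min, seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize network weights
#'
#' Uniform(-0.5, 0.5) entries scaled by 1/sqrt(fan-in), drawn from a seeded
#' stream so training is reproducible.
#'
#' @param n_in input dimension (number of independent components).
#' @param hidden_units hidden layer size.
#' @param seed integer seed.
#' @return Object of class `nn_model` with `W_h` (hidden x n_in), `b_h`,
#'   `W_o` (2 x hidden), `b_o`.
#' @export
nn_init <- function(n_in, hidden_units = 80L, seed = 1L) {
  with_seed(seed, {
    W_h <- matrix(stats::runif(hidden_units * n_in, -0.5, 0.5) / sqrt(n_in),
                  hidden_units, n_in)
    b_h <- stats::runif(hidden_units, -0.5, 0.5) / sqrt(n_in)
    W_o <- matrix(stats::runif(2 * hidden_units, -0.5, 0.5) /
                    sqrt(hidden_units), 2, hidden_units)
    b_o <- stats::runif(2, -0.5, 0.5) / sqrt(hidden_units)
    structure(list(W_h = W_h, b_h = b_h, W_o = W_o, b_o = b_o),
              class = "nn_model")
  })
}

#' Forward pass of the classifier network
#'
#' `out = tanh(W_o %*% tanh(W_h %*% S + b_h) + b_o)`; every entry lies in
#' (-1, 1). Row 1 is the walking unit, row 2 the perturbation unit.
#'
#' @param model an `nn_model`.
#' @param S component matrix, `n_in` x samples.
#' @return Raw output matrix, 2 x samples.
#' @export
nn_forward <- function(model, S) {
  stopifnot(inherits(model, "nn_model"))
  S <- as.matrix(S)
  if (nrow(S) != ncol(model$W_h)) {
    stop("input dimension ", nrow(S), " does not match network (",
         ncol(model$W_h), ")")
  }
  H <- tanh(model$W_h %*% S + model$b_h)
  tanh(model$W_o %*% H + model$b_o)
}

#' One resilient-backpropagation update
#'
#' Per-weight adaptive steps: when the gradient keeps its sign the step
#' grows by `eta_plus` (capped at `delta_max`); when it flips the step
#' shrinks by `eta_minus` (floored at `delta_min`) and the gradient memory
#' is zeroed. The weight always moves by `-sign(gradient) * step`. This is
#' the same rule the compiled training loop applies.
#'
#' @param w numeric weights (any shape).
#' @param grad gradient of the loss with respect to `w`.
#' @param state `NULL` on the first call, else the state returned last time.
#' @param eta_plus,eta_minus,delta0,delta_max,delta_min Rprop constants.
#' @return List with updated `w` and `state` (`delta`, `prev`).
#' @export
rprop_step <- function(w, grad, state = NULL, eta_plus = 1.2,
                       eta_minus = 0.5, delta0 = 0.07, delta_max = 50,
                       delta_min = 1e-6) {
  if (is.null(state)) {
    zero <- w * 0
    state <- list(delta = zero + delta0, prev = zero)
  }
  prod <- grad * state$prev
  delta <- state$delta
  delta[prod > 0] <- pmin(delta[prod > 0] * eta_plus, delta_max)
  delta[prod < 0] <- pmax(delta[prod < 0] * eta_minus, delta_min)
  w <- w - sign(grad) * delta
  prev <- grad
  prev[prod < 0] <- 0
  list(w = w, state = list(delta = delta, prev = prev))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode W/P labels as +/-1 one-hot targets
#'
#' @param label factor or character vector over `W`/`P`.
#' @return Matrix 2 x length(label): column (+1, -1) for W, (-1, +1) for P.
#' @export
encode_targets <- function(label) {
  lab <- as.character(label)
  if (!all(lab %in% c("W", "P"))) stop("labels must be W or P")
  rbind(ifelse(lab == "W", 1, -1), ifelse(lab == "P", 1, -1))
}

#' Train the network with Rprop and early stopping
#'
#' Full-batch Rprop on the mean squared error of the +/-1 targets. The
#' validation set is evaluated after every epoch and the weights from the
#' epoch with minimal validation error are returned; training stops after
#' `patience` epochs without improvement or at `max_epochs`. Deterministic
#' given `cfg$seed`.
#'
#' @param S_train,label_train training components (`n_in` x T) and labels.
#' @param S_val,label_val validation components and labels (the held-out
#'   inner-fold trial).
#' @param cfg a [train_config()].
#' @return An `nn_model` carrying a `log` attribute with per-epoch
#'   training/validation MSE, the best epoch and the epochs run.
#' @export
train_nn <- function(S_train, label_train, S_val, label_val,
                     cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  S_train <- as.matrix(S_train); S_val <- as.matrix(S_val)
  if (ncol(S_train) == 0 || ncol(S_val) == 0) {
    stop("training and validation sets must be non-empty")
  }
  Y <- encode_targets(label_train)
  Yv <- encode_targets(label_val)
  init <- nn_init(nrow(S_train), cfg$hidden_units, cfg$seed)
  fit <- rprop_train_cpp(init$W_h, init$b_h, init$W_o, init$b_o,
                         S_train, Y, S_val, Yv,
                         cfg$max_epochs, cfg$patience, cfg$eta_plus,
                         cfg$eta_minus, cfg$delta0, cfg$delta_max,
                         cfg$delta_min)
  model <- structure(list(W_h = fit$W_h, b_h = as.vector(fit$b_h),
                          W_o = fit$W_o, b_o = as.vector(fit$b_o)),
                     class = "nn_model")
  attr(model, "log") <- list(train_mse = fit$train_mse,
                             val_mse = fit$val_mse,
                             best_epoch = fit$best_epoch,
                             best_val_mse = fit$best_val_mse,
                             epochs_run = fit$epochs_run)
  model
}

#' @export
print.nn_model <- function(x, ...) {
  log <- attr(x, "log")
  cat(sprintf("nn_model: %d -> %d -> 2 (tanh)\n",
              ncol(x$W_h), nrow(x$W_h)))
  if (!is.null(log)) {
    cat(sprintf("  trained %d epochs, best epoch %d (val MSE %.4g)\n",
                log$epochs_run, log$best_epoch, log$best_val_mse))
  }
  invisible(x)
}

#' Serialize a trained network to JSON
#'
#' @param model an `nn_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_nn_json <- function(model, path) {
  stopifnot(inherits(model, "nn_model"))
  jsonlite::write_json(
    list(W_h = model$W_h, b_h = model$b_h, W_o = model$W_o,
         b_o = model$b_o, log = attr(model, "log")),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a network written by [write_nn_json()]
#' @param path JSON path.
#' @return An `nn_model`.
#' @export
read_nn_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- structure(list(W_h = x$W_h, b_h = as.vector(x$b_h), W_o = x$W_o,
                      b_o = as.vector(x$b_o)), class = "nn_model")
  attr(m, "log") <- x$log
  m
}
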