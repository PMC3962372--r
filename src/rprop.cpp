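// Full-batch resilient-backpropagation (Rprop) training of the
// three-layer tanh network. The epoch loop lives here because the nested
// leave-one-out design trains hundreds of networks per subject; the
// update rule is identical to the R-level rprop_step().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// elementwise Rprop update without weight backtracking: on a gradient sign
// flip the step shrinks and the gradient memory is zeroed, but the step is
// still applied
static void rprop_update(mat& w, const mat& g, mat& delta, mat& prev,
                         double ep, double em, double dmax, double dmin) {
  for (uword k = 0; k < w.n_elem; ++k) {
    const double gr = g[k];
    const double prod = gr * prev[k];
    if (prod > 0.0) {
      delta[k] = std::min(delta[k] * ep, dmax);
    } else if (prod < 0.0) {
      delta[k] = std::max(delta[k] * em, dmin);
    }
    const double s = (gr > 0.0) - (gr < 0.0);
    w[k] -= s * delta[k];
    prev[k] = (prod < 0.0) ? 0.0 : gr;
  }
}

static double mse(const mat& O, const mat& Y) {
  return accu(square(O - Y)) / O.n_elem;
}

// tanh(W * X + b) with the bias broadcast across columns
static mat layer(const mat& W, const mat& X, const vec& b) {
  mat Z = W * X;
  Z.each_col() += b;
  return tanh(Z);
}

// [[Rcpp::export]]
Rcpp::List rprop_train_cpp(arma::mat W_h, arma::vec b_h,
                           arma::mat W_o, arma::vec b_o,
                           const arma::mat& S, const arma::mat& Y,
                           const arma::mat& Sv, const arma::mat& Yv,
                           int max_epochs, int patience,
                           double eta_plus, double eta_minus,
                           double delta0, double delta_max,
                           double delta_min) {
  const double n_out = static_cast<double>(Y.n_elem);

  mat dWh(size(W_h), fill::value(delta0)), pWh(size(W_h), fill::zeros);
  mat dbh(size(b_h), fill::value(delta0)), pbh(size(b_h), fill::zeros);
  mat dWo(size(W_o), fill::value(delta0)), pWo(size(W_o), fill::zeros);
  mat dbo(size(b_o), fill::value(delta0)), pbo(size(b_o), fill::zeros);

  mat best_Wh = W_h, best_Wo = W_o;
  vec best_bh = b_h, best_bo = b_o;
  double best_val = datum::inf;
  int best_epoch = 0, since_best = 0, epochs_run = 0;
  std::vector<double> train_log, val_log;

  // buffers reused across epochs (the inner LOOCV calls this hundreds of
  // times on ~10^4-sample batches; avoid reallocating per epoch)
  mat H, O, dO, dH, gWo, gWh;
  vec gbo, gbh;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // forward; the training loss is logged at the epoch's entry weights
    H = W_h * S;
    H.each_col() += b_h;
    H = tanh(H);
    O = W_o * H;
    O.each_col() += b_o;
    O = tanh(O);
    train_log.push_back(mse(O, Y));

    // backprop of mean squared error over all output entries
    dO = (2.0 / n_out) * (O - Y) % (1.0 - square(O));
    gWo = dO * H.t();
    gbo = sum(dO, 1);
    dH = W_o.t() * dO;
    dH %= (1.0 - square(H));
    gWh = dH * S.t();
    gbh = sum(dH, 1);

    rprop_update(W_h, gWh, dWh, pWh, eta_plus, eta_minus, delta_max, delta_min);
    { mat bh(b_h.memptr(), b_h.n_elem, 1, false, true);
      mat gb(gbh.memptr(), gbh.n_elem, 1, false, true);
      rprop_update(bh, gb, dbh, pbh, eta_plus, eta_minus, delta_max, delta_min); }
    rprop_update(W_o, gWo, dWo, pWo, eta_plus, eta_minus, delta_max, delta_min);
    { mat bo(b_o.memptr(), b_o.n_elem, 1, false, true);
      mat gb(gbo.memptr(), gbo.n_elem, 1, false, true);
      rprop_update(bo, gb, dbo, pbo, eta_plus, eta_minus, delta_max, delta_min); }

    // post-update validation loss drives the early-stopping checkpoint
    mat Hv = layer(W_h, Sv, b_h);
    mat Ov = layer(W_o, Hv, b_o);
    double val = mse(Ov, Yv);
    val_log.push_back(val);
    epochs_run = epoch;

    if (val < best_val) {
      best_val = val;
      best_epoch = epoch;
      best_Wh = W_h; best_bh = b_h; best_Wo = W_o; best_bo = b_o;
      since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W_h") = best_Wh, Rcpp::Named("b_h") = best_bh,
    Rcpp::Named("W_o") = best_Wo, Rcpp::Named("b_o") = best_bo,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_mse") = best_val,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("train_mse") = train_log,
    Rcpp::Named("val_mse") = val_log);
}
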