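// Standalone differentiable sub-paths used for finite-difference gradient
// verification: (a) sub-threshold CUBA dynamics, where the map from weights
// to summed membrane potential is smooth; (b) the trace -> STDP ->
// eligibility -> modulated-weight chain with spike rasters frozen as data,
// where the map from (eta, alpha_e, retentions, modulation path) to the
// final weights is smooth.
#include "tape.h"
using namespace Rcpp;
using mspk::Tape;
using mspk::CubaCfg;

// [[Rcpp::export]]
List lif_chain_grad_cpp(arma::mat W, arma::mat raster, List cfg) {
  CubaCfg p;
  p.alpha_u = as<double>(cfg["alpha_u"]);
  p.alpha_v = as<double>(cfg["alpha_v"]);
  p.u_rest = as<double>(cfg["u_rest"]);
  p.v_rest = as<double>(cfg["v_rest"]);
  p.R = as<double>(cfg["R"]);
  p.v_th = as<double>(cfg["v_th"]);
  p.post_update_u = as<bool>(cfg["post_update_u"]);
  p.surr_shape = as<int>(cfg["surr_shape"]);
  p.surr_scale = as<double>(cfg["surr_scale"]);
  p.surr_amp = as<double>(cfg["surr_amp"]);

  const int T = raster.n_cols;
  Tape tp;
  tp.reserve(static_cast<size_t>(T) * 16 + 8);
  int Wn = tp.leaf(W, true);
  int u = tp.leaf(arma::mat(W.n_rows, 1, arma::fill::value(p.u_rest)));
  int v = tp.leaf(arma::mat(W.n_rows, 1, arma::fill::value(p.v_rest)));
  int loss = tp.leaf(arma::zeros(1, 1), false);
  int n_spikes = 0;
  for (int t = 0; t < T; ++t) {
    int s_in = tp.leaf(raster.col(t));
    int s = mspk::cuba_step(tp, u, v, tp.matmul(Wn, s_in), p);
    n_spikes += static_cast<int>(arma::accu(tp.val(s)));
    loss = tp.add(loss, tp.sumall(v));
  }
  tp.backward(loss);
  return List::create(_["loss"] = tp.val(loss)(0, 0),
                      _["n_spikes"] = n_spikes,
                      _["grad_W"] = wrap(tp.grad_of(Wn)));
}

// [[Rcpp::export]]
List plastic_chain_grad_cpp(List params, arma::mat s_pre, arma::mat s_post,
                            arma::mat Mp, arma::mat Mm, arma::mat loss_w,
                            bool triplet) {
  const int T = s_pre.n_cols;
  const int n_pre = s_pre.n_rows, n_post = s_post.n_rows;
  Tape tp;
  tp.reserve(static_cast<size_t>(T) * 30 + 16);

  CharacterVector nm = params.names();
  std::vector<std::string> names(nm.size());
  std::vector<int> pid(nm.size());
  for (int k = 0; k < nm.size(); ++k) {
    names[k] = as<std::string>(nm[k]);
    pid[k] = tp.leaf(as<arma::mat>(params[k]), true);
  }
  auto P = [&](const char* key) {
    for (size_t k = 0; k < names.size(); ++k)
      if (names[k] == key) return pid[k];
    stop("missing parameter: %s", key);
    return -1;
  };
  int eta_p = P("eta_p"), eta_m = P("eta_m"), alpha_e = P("alpha_e");
  int gamma = P("gamma"), ax = P("alpha_x"), atau = P("alpha_tau");
  int beta = P("beta");
  int Mpn = tp.leaf(Mp, true), Mmn = tp.leaf(Mm, true);

  int W = P("W0");
  int x_pre = tp.leaf(arma::zeros(n_pre, 1));
  int x_post = tp.leaf(arma::zeros(n_post, 1));
  int x_slow = tp.leaf(arma::zeros(n_post, 1));
  int E_p = tp.leaf(arma::zeros(n_post, n_pre));
  int E_m = tp.leaf(arma::zeros(n_post, n_pre));

  for (int t = 0; t < T; ++t) {
    int sp = tp.leaf(s_pre.col(t));
    int so = tp.leaf(s_post.col(t));
    int x_slow_prev = x_slow;
    x_pre = tp.add(tp.bmul(ax, x_pre), tp.bmul(beta, sp));
    x_post = tp.add(tp.bmul(ax, x_post), tp.bmul(beta, so));
    int d_plus;
    if (triplet) {
      x_slow = tp.add(tp.bmul(atau, x_slow), tp.bmul(beta, so));
      d_plus = tp.emul(eta_p, tp.outer(tp.emul(so, x_slow_prev), x_pre));
    } else {
      d_plus = tp.emul(eta_p, tp.outer(so, x_pre));
    }
    int d_minus = tp.emul(eta_m, tp.outer(x_post, sp));
    E_p = tp.add(tp.bmul(gamma, E_p), tp.emul(alpha_e, d_plus));
    E_m = tp.add(tp.bmul(gamma, E_m), tp.emul(alpha_e, d_minus));
    int dW = tp.sub(tp.colbc(tp.colsel(Mpn, t), E_p),
                    tp.colbc(tp.colsel(Mmn, t), E_m));
    W = tp.add(W, dW);
  }
  int loss = tp.sumall(tp.mulcm(W, loss_w));
  tp.backward(loss);

  List grads;
  for (size_t k = 0; k < names.size(); ++k)
    grads[names[k]] = wrap(tp.grad_of(pid[k]));
  grads["Mp"] = wrap(tp.grad_of(Mpn));
  grads["Mm"] = wrap(tp.grad_of(Mmn));
  return List::create(_["loss"] = tp.val(loss)(0, 0),
                      _["W_final"] = wrap(tp.val(W)),
                      _["grads"] = grads);
}
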