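// Differentiable inner loop for the cue-association system: the plastic
// DP-SNN (input -> 48 hidden CUBA -> 2 action readouts) coupled with the
// non-plastic NM-SNN (sensory ++ hidden ++ feedback -> 2 x 64 CUBA -> linear
// head -> low-pass per-input LTP/LTD modulation).  One call simulates a full
// multi-trial episode with no intra-episode resets and, on request,
// backpropagates the test-trial loss through every time step, the plasticity
// recurrences, and the surrogate spike derivatives.
//
// Trainable constants travel in raw (unconstrained) form and are mapped on
// the tape: retentions through a logistic, rates through exp, so gradient
// steps can never push them out of range.
#include "tape.h"
using namespace Rcpp;
using mspk::Tape;
using mspk::CubaCfg;

static CubaCfg read_cuba(const List& cfg) {
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
  return p;
}

// [[Rcpp::export]]
List cue_inner_cpp(List omega, List episode, List cfg) {
  const arma::mat raster = as<arma::mat>(episode["raster"]);
  const arma::mat fb = as<arma::mat>(episode["fb"]);
  const int label = as<int>(episode["label"]);      // 1 = right, 2 = left
  const int win0 = as<int>(episode["win0"]) - 1;    // test decision window
  const int win1 = as<int>(episode["win1"]) - 1;
  const arma::vec gate = as<arma::vec>(episode["gate"]);

  const arma::mat signmask = as<arma::mat>(cfg["signmask"]);
  const arma::mat maskm = as<arma::mat>(cfg["mask"]);
  const bool plastic = as<bool>(cfg["plastic"]);
  const bool triplet = as<int>(cfg["rule"]) == 1;
  const bool want_grad = as<bool>(cfg["want_grad"]);
  const bool want_diag = as<bool>(cfg["want_diag"]);
  const CubaCfg np = read_cuba(cfg);

  const int n_in = raster.n_rows;
  const int T = raster.n_cols;
  const int n_hid = signmask.n_rows;
  if (win0 < 0 || win1 >= T || win1 < win0)
    stop("degenerate test decision window");

  Tape tp;
  tp.reserve(static_cast<size_t>(T) * 70 + 64);

  // parameter leaves
  CharacterVector nm = omega.names();
  std::vector<std::string> names(nm.size());
  std::vector<int> pid(nm.size());
  for (int k = 0; k < nm.size(); ++k) {
    names[k] = as<std::string>(nm[k]);
    pid[k] = tp.leaf(as<arma::mat>(omega[k]), want_grad);
  }
  auto P = [&](const char* key) {
    for (size_t k = 0; k < names.size(); ++k)
      if (names[k] == key) return pid[k];
    stop("missing meta parameter: %s", key);
    return -1;
  };

  const int W_nm1 = P("W_nm1"), W_nm2 = P("W_nm2");
  const int W_head = P("W_head"), b_head = P("b_head");
  const int W_ro = P("W_ro");
  const int gain = tp.expop(P("gain_raw"));
  const int bias_ro = P("bias_ro");
  const int n_out = tp.val(W_ro).n_rows;

  int W_cur = tp.mulcm(P("W0"), maskm);
  int eta_p = -1, eta_m = -1, alpha_e = -1;
  int gamma = -1, ax = -1, atau = -1, beta = -1, lam = -1;
  if (plastic) {
    eta_p = tp.mulcm(tp.expop(P("log_eta_p")), maskm);
    eta_m = tp.mulcm(tp.expop(P("log_eta_m")), maskm);
    alpha_e = P("alpha_e");
    gamma = tp.sigmoid(P("gamma_raw"));
    ax = tp.sigmoid(P("ax_raw"));
    atau = tp.sigmoid(P("atau_raw"));
    beta = tp.expop(P("beta_raw"));
    lam = tp.sigmoid(P("lam_raw"));
  }

  // state nodes (constant leaves at rest; chains grow per step)
  auto zeros_leaf = [&](int n) { return tp.leaf(arma::zeros(n, 1)); };
  int u_h = tp.leaf(arma::mat(n_hid, 1, arma::fill::value(np.u_rest)));
  int v_h = tp.leaf(arma::mat(n_hid, 1, arma::fill::value(np.v_rest)));
  const int n_nm1 = tp.val(W_nm1).n_rows, n_nm2 = tp.val(W_nm2).n_rows;
  int u1 = tp.leaf(arma::mat(n_nm1, 1, arma::fill::value(np.u_rest)));
  int v1 = tp.leaf(arma::mat(n_nm1, 1, arma::fill::value(np.v_rest)));
  int u2 = tp.leaf(arma::mat(n_nm2, 1, arma::fill::value(np.u_rest)));
  int v2 = tp.leaf(arma::mat(n_nm2, 1, arma::fill::value(np.v_rest)));
  int x_pre = zeros_leaf(n_in), x_post = zeros_leaf(n_hid);
  int x_post_slow = zeros_leaf(n_hid);
  int E_p = tp.leaf(arma::zeros(n_hid, n_in));
  int E_m = tp.leaf(arma::zeros(n_hid, n_in));
  int m_prev = zeros_leaf(2 * n_in);
  int acc = tp.leaf(arma::zeros(n_out, 1));

  arma::mat hid_raster, mod_stream;
  arma::vec dw_max;
  if (want_diag) {
    hid_raster.zeros(n_hid, T);
    mod_stream.zeros(2 * n_in, T);
    dw_max.zeros(T);
  }

  for (int t = 0; t < T; ++t) {
    int s_in = tp.leaf(raster.col(t));
    int W_eff = tp.mulcm(tp.relu(W_cur), signmask);
    int s_h = mspk::cuba_step(tp, u_h, v_h, tp.matmul(W_eff, s_in), np);
    if (t >= win0 && t <= win1)
      acc = tp.add(acc, tp.matmul(W_ro, s_h));

    int Mp = -1, Mm = -1;
    if (plastic) {
      int fb_t = tp.leaf(fb.col(t));
      int z_in = tp.vcat3(s_in, s_h, fb_t);
      int s1 = mspk::cuba_step(tp, u1, v1, tp.matmul(W_nm1, z_in), np);
      int s2 = mspk::cuba_step(tp, u2, v2, tp.matmul(W_nm2, s1), np);
      int raw = tp.add(tp.matmul(W_head, s2), b_head);
      int m_t = tp.add(tp.bmul(lam, m_prev), raw);
      m_prev = m_t;
      Mp = tp.rowsel(m_t, 0, n_in - 1);
      Mm = tp.rowsel(m_t, n_in, 2 * n_in - 1);

      int x_slow_prev = x_post_slow;
      x_pre = tp.add(tp.bmul(ax, x_pre), tp.bmul(beta, s_in));
      x_post = tp.add(tp.bmul(ax, x_post), tp.bmul(beta, s_h));
      int d_plus;
      if (triplet) {
        x_post_slow = tp.add(tp.bmul(atau, x_post_slow), tp.bmul(beta, s_h));
        d_plus = tp.emul(eta_p, tp.outer(tp.emul(s_h, x_slow_prev), x_pre));
      } else {
        d_plus = tp.emul(eta_p, tp.outer(s_h, x_pre));
      }
      int d_minus = tp.emul(eta_m, tp.outer(x_post, s_in));
      E_p = tp.add(tp.bmul(gamma, E_p), tp.emul(alpha_e, d_plus));
      E_m = tp.add(tp.bmul(gamma, E_m), tp.emul(alpha_e, d_minus));

      if (gate(t) != 0.0) {
        int dW = tp.sub(tp.colbc(Mp, E_p), tp.colbc(Mm, E_m));
        W_cur = tp.add(W_cur, dW);
        if (want_diag) dw_max(t) = arma::abs(tp.val(dW)).max();
      }
    }

    if (want_diag) {
      hid_raster.col(t) = tp.val(s_h).col(0);
      if (plastic) mod_stream.col(t) = tp.val(m_prev).col(0);
    }
    if (!tp.val(v_h).is_finite())
      stop("non-finite membrane potential at step %d: numerical divergence",
           t + 1);
  }

  int z = tp.badd(bias_ro, tp.bmul(gain, acc));
  int loss_id = tp.sub(tp.sumall(tp.softplus(z)), tp.pick(z, label - 1));

  arma::vec accv = tp.val(acc).col(0);
  arma::vec zv = tp.val(z).col(0);
  arma::vec p = 1.0 / (1.0 + arma::exp(-zv));
  int choice = static_cast<int>(accv.index_max()) + 1;  // first max wins ties

  List grads;
  if (want_grad) {
    tp.backward(loss_id);
    for (size_t k = 0; k < names.size(); ++k)
      grads[names[k]] = wrap(tp.grad_of(pid[k]));
  }

  List out = List::create(
    _["loss"] = tp.val(loss_id)(0, 0),
    _["correct"] = (choice == label) ? 1.0 : 0.0,
    _["choice"] = choice,
    _["p"] = wrap(p),
    _["acc"] = wrap(accv),
    _["grads"] = grads);
  if (want_diag) {
    out["hidden"] = wrap(hid_raster);
    out["modulation"] = wrap(mod_stream);
    out["W_final"] = wrap(tp.val(W_cur));
    out["dw_max"] = wrap(dw_max);
  }
  return out;
}
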