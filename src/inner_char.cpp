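// Differentiable inner loop for the sequential character-recognition system:
// a small convolutional encoder (conv 1->4 k3 pad1, per-image channel norm,
// ReLU, 2x2 max-pool, conv 4->4 k3 pad1, norm, ReLU, pool, flatten to 196)
// injects current into 196 CUBA input neurons; the DP-SNN (196 -> 48 hidden,
// triplet-STDP plastic) reads out through one recognition neuron whose
// activity is summed within each phase-2 window; the NM-SNN (input ++ hidden
// -> 2 x 64 CUBA) emits per-input LTP/LTD modulation that is gated to the
// phase-1 presentation window only.  Weights are therefore frozen outside
// phase 1, so the plasticity and neuromodulation tape is only built there.
#include "tape.h"
using namespace Rcpp;
using mspk::Tape;
using mspk::CubaCfg;

static CubaCfg read_cuba_cfg(const List& cfg) {
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

// im2col indices (1-based into the flattened input, 0 = zero padding) for a
// 3x3 same convolution over an H x W grid with n_ch input channels stored as
// an (n_ch x H*W) matrix (arma column-major).
static arma::umat im2col3(int H, int W, int n_ch) {
  arma::umat idx(9 * n_ch, H * W, arma::fill::zeros);
  for (int c = 1; c <= W; ++c) {
    for (int r = 1; r <= H; ++r) {
      int j = (c - 1) * H + r;  // output column, 1-based
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr < 1 || rr > H || cc < 1 || cc > W) continue;
          int pix = (cc - 1) * H + rr;
          int kk = (dc + 1) * 3 + (dr + 1) + 1;
          for (int ch = 1; ch <= n_ch; ++ch)
            idx((ch - 1) * 9 + kk - 1, j - 1) =
              static_cast<arma::uword>((pix - 1) * n_ch + ch);
        }
      }
    }
  }
  return idx;
}

// candidate columns for 2x2/2 max pooling over an H x W grid
static arma::umat pool2idx(int H, int W) {
  int Ho = H / 2, Wo = W / 2;
  arma::umat cand(4, Ho * Wo);
  for (int c = 1; c <= Wo; ++c) {
    for (int r = 1; r <= Ho; ++r) {
      int j = (c - 1) * Ho + r;
      int k = 0;
      for (int dc = 0; dc <= 1; ++dc)
        for (int dr = 0; dr <= 1; ++dr)
          cand(k++, j - 1) =
            static_cast<arma::uword>((2 * c - 2 + dc) * H + (2 * r - 1 + dr));
    }
  }
  return cand;
}

// [[Rcpp::export]]
List char_inner_cpp(List omega, List episode, List cfg) {
  const arma::mat images = as<arma::mat>(episode["images"]);  // 784 x 6
  const int slot = as<int>(episode["slot"]);                  // 1..n_phase2
  const int t_image = as<int>(episode["t_image"]);
  const int n_phase2 = as<int>(episode["n_phase2"]);

  const arma::mat signmask = as<arma::mat>(cfg["signmask"]);
  const arma::mat maskm = as<arma::mat>(cfg["mask"]);
  const bool plastic = as<bool>(cfg["plastic"]);
  const bool want_grad = as<bool>(cfg["want_grad"]);
  const bool want_diag = as<bool>(cfg["want_diag"]);
  const CubaCfg np = read_cuba_cfg(cfg);

  const int side = 28;
  const int n_in = side * side / 4;  // 196 after two 2x2 pools
  const int n_hid = signmask.n_rows;
  const int n_img = 1 + n_phase2;
  const int T = n_img * t_image;
  if (static_cast<int>(images.n_rows) != side * side ||
      static_cast<int>(images.n_cols) != n_img)
    stop("images must be %d x %d", side * side, n_img);
  if (static_cast<int>(signmask.n_cols) != n_in)
    stop("plastic layer must have %d presynaptic inputs", n_in);

  const arma::umat idx1 = im2col3(side, side, 1);
  const arma::umat cand1 = pool2idx(side, side);
  const arma::umat idx2 = im2col3(side / 2, side / 2, 4);
  const arma::umat cand2 = pool2idx(side / 2, side / 2);

  Tape tp;
  tp.reserve(static_cast<size_t>(T) * 40 +
             static_cast<size_t>(t_image) * 40 + 200);

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

  // encoder: one pass per episode image
  const int K1 = P("K1"), K2 = P("K2");
  const int g1 = P("bn1_gamma"), b1 = P("bn1_beta");
  const int g2 = P("bn2_gamma"), b2 = P("bn2_beta");
  std::vector<int> enc(n_img);
  for (int j = 0; j < n_img; ++j) {
    int x = tp.leaf(images.col(j));
    int c1 = tp.matmul(K1, tp.gather(x, idx1));                 // 4 x 784
    int r1 = tp.relu(tp.rowadd(b1, tp.rowbc(g1, tp.rownorm(c1))));
    int p1 = tp.pool(r1, cand1);                                // 4 x 196
    int c2 = tp.matmul(K2, tp.gather(p1, idx2));                // 4 x 196
    int r2 = tp.relu(tp.rowadd(b2, tp.rowbc(g2, tp.rownorm(c2))));
    int p2 = tp.pool(r2, cand2);                                // 4 x 49
    enc[j] = tp.reshape(p2, n_in, 1);
  }

  const int W_nm1 = P("W_nm1"), W_nm2 = P("W_nm2");
  const int W_head = P("W_head"), b_head = P("b_head");
  const int W_ro = P("W_ro");
  const int gain = tp.expop(P("gain_raw"));

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

  auto zeros_leaf = [&](int n) { return tp.leaf(arma::zeros(n, 1)); };
  int u_in = tp.leaf(arma::mat(n_in, 1, arma::fill::value(np.u_rest)));
  int v_in = tp.leaf(arma::mat(n_in, 1, arma::fill::value(np.v_rest)));
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
  std::vector<int> win_acc(n_phase2, -1);

  arma::mat hid_raster, in_raster, mod_stream;
  if (want_diag) {
    hid_raster.zeros(n_hid, T);
    in_raster.zeros(n_in, T);
    mod_stream.zeros(2 * n_in, T);
  }

  for (int t = 0; t < T; ++t) {
    int img = t / t_image;               // 0 = phase 1, 1.. = phase 2 slots
    bool gate_on = plastic && img == 0;  // modulation only during phase 1

    int s_in = mspk::cuba_step(tp, u_in, v_in, enc[img], np);
    int W_eff = tp.mulcm(tp.relu(W_cur), signmask);
    int s_h = mspk::cuba_step(tp, u_h, v_h, tp.matmul(W_eff, s_in), np);
    if (img >= 1) {
      int r = tp.matmul(W_ro, s_h);      // 1 x 1 recognition readout
      int k = img - 1;
      win_acc[k] = (win_acc[k] < 0) ? r : tp.add(win_acc[k], r);
    }

    if (gate_on) {
      int z_in = tp.vcat2(s_in, s_h);
      int s1 = mspk::cuba_step(tp, u1, v1, tp.matmul(W_nm1, z_in), np);
      int s2 = mspk::cuba_step(tp, u2, v2, tp.matmul(W_nm2, s1), np);
      int raw = tp.add(tp.matmul(W_head, s2), b_head);
      int m_t = tp.add(tp.bmul(lam, m_prev), raw);
      m_prev = m_t;
      int Mp = tp.rowsel(m_t, 0, n_in - 1);
      int Mm = tp.rowsel(m_t, n_in, 2 * n_in - 1);

      int x_slow_prev = x_post_slow;
      x_pre = tp.add(tp.bmul(ax, x_pre), tp.bmul(beta, s_in));
      x_post = tp.add(tp.bmul(ax, x_post), tp.bmul(beta, s_h));
      x_post_slow = tp.add(tp.bmul(atau, x_post_slow), tp.bmul(beta, s_h));
      int d_plus = tp.emul(eta_p, tp.outer(tp.emul(s_h, x_slow_prev), x_pre));
      int d_minus = tp.emul(eta_m, tp.outer(x_post, s_in));
      E_p = tp.add(tp.bmul(gamma, E_p), tp.emul(alpha_e, d_plus));
      E_m = tp.add(tp.bmul(gamma, E_m), tp.emul(alpha_e, d_minus));
      W_cur = tp.add(W_cur, tp.sub(tp.colbc(Mp, E_p), tp.colbc(Mm, E_m)));
      if (want_diag) mod_stream.col(t) = tp.val(m_prev).col(0);
    }

    if (want_diag) {
      hid_raster.col(t) = tp.val(s_h).col(0);
      in_raster.col(t) = tp.val(s_in).col(0);
    }
    if (!tp.val(v_h).is_finite())
      stop("non-finite membrane potential at step %d: numerical divergence",
           t + 1);
  }

  int z0 = win_acc[0];
  for (int k = 1; k < n_phase2; ++k) z0 = tp.vcat2(z0, win_acc[k]);
  int z = tp.bmul(gain, z0);
  int loss_id = tp.sub(tp.logsumexp(z), tp.pick(z, slot - 1));

  arma::vec sums = tp.val(z0).col(0);
  int choice = static_cast<int>(sums.index_max()) + 1;  // first max wins ties

  List grads;
  if (want_grad) {
    tp.backward(loss_id);
    for (size_t k = 0; k < names.size(); ++k)
      grads[names[k]] = wrap(tp.grad_of(pid[k]));
  }

  List out = List::create(
    _["loss"] = tp.val(loss_id)(0, 0),
    _["correct"] = (choice == slot) ? 1.0 : 0.0,
    _["choice"] = choice,
    _["window_sums"] = wrap(sums),
    _["grads"] = grads);
  if (want_diag) {
    out["hidden"] = wrap(hid_raster);
    out["input_spikes"] = wrap(in_raster);
    out["modulation"] = wrap(mod_stream);
    out["W_final"] = wrap(tp.val(W_cur));
    arma::mat encm(n_in, n_img);
    for (int j = 0; j < n_img; ++j) encm.col(j) = tp.val(enc[j]).col(0);
    out["encodings"] = wrap(encm);
  }
  return out;
}
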