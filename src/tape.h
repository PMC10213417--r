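// Minimal reverse-mode autodiff tape over Armadillo matrices.
//
// Backpropagation through time over spiking dynamics needs a custom backward
// rule for the threshold nonlinearity (surrogate gradient), so the engine is
// written here rather than borrowed: a flat tape of nodes, each holding its
// value, an opcode, parent indices and whatever the backward pass needs.
// Gradients are accumulated lazily (dead branches cost nothing on the way
// back).  All vectors are column vectors; weight matrices are (post x pre).
#ifndef METASPIKE_TAPE_H
#define METASPIKE_TAPE_H

#include <RcppArmadillo.h>
#include <vector>

namespace mspk {

enum Op {
  LEAF, ADD, SUB, EMUL, MATMUL, OUTER, SMUL, ADDC, BMUL, BADD,
  ROWBC, COLBC, ROWADD, VCAT2, VCAT3, ROWSEL, COLSEL, SIGMOID, EXPOP, RELU,
  SOFTPLUS, SPIKE, SUMALL, LOGSUMEXP, PICK, MULCM, GATHER, POOL,
  ROWNORM, RESHAPE
};

struct Node {
  arma::mat val;
  arma::mat grad;    // allocated on first accumulation
  Op op = LEAF;
  int a = -1, b = -1;
  double c = 0.0;
  int i0 = 0, i1 = 0;
  arma::mat aux;
  bool needs = false;  // does anything upstream require a gradient here?
};

struct Tape {
  std::vector<Node> nodes;

  void reserve(size_t n) { nodes.reserve(n); }
  const arma::mat& val(int id) const { return nodes[id].val; }

  int push(Node&& nd) {
    nodes.push_back(std::move(nd));
    return static_cast<int>(nodes.size()) - 1;
  }
  bool needs(int id) const { return id >= 0 && nodes[id].needs; }

  int leaf(const arma::mat& v, bool requires_grad = false) {
    Node nd; nd.val = v; nd.op = LEAF; nd.needs = requires_grad;
    return push(std::move(nd));
  }

  int make(Op op, int a, int b, arma::mat&& v) {
    Node nd; nd.op = op; nd.a = a; nd.b = b; nd.val = std::move(v);
    nd.needs = needs(a) || needs(b);
    return push(std::move(nd));
  }

  int add(int a, int b) { return make(ADD, a, b, nodes[a].val + nodes[b].val); }
  int sub(int a, int b) { return make(SUB, a, b, nodes[a].val - nodes[b].val); }
  int emul(int a, int b) { return make(EMUL, a, b, nodes[a].val % nodes[b].val); }
  int matmul(int a, int b) { return make(MATMUL, a, b, nodes[a].val * nodes[b].val); }
  // outer product of column vectors a (n x 1), b (m x 1) -> (n x m)
  int outer(int a, int b) { return make(OUTER, a, b, nodes[a].val * nodes[b].val.t()); }
  int smul(int a, double c) {
    int id = make(SMUL, a, -1, c * nodes[a].val); nodes[id].c = c; return id;
  }
  int addc(int a, double c) {
    if (c == 0.0) return a;
    int id = make(ADDC, a, -1, nodes[a].val + c); nodes[id].c = c; return id;
  }
  // broadcast ops with a 1x1 scalar node s
  int bmul(int s, int a) { return make(BMUL, s, a, nodes[s].val(0, 0) * nodes[a].val); }
  int badd(int s, int a) { return make(BADD, s, a, nodes[s].val(0, 0) + nodes[a].val); }
  // v (n x 1) scales the rows of m (n x k)
  int rowbc(int v, int m) {
    arma::mat out = nodes[m].val;
    out.each_col() %= arma::vec(nodes[v].val.col(0));
    return make(ROWBC, v, m, std::move(out));
  }
  // v (k x 1) scales the columns of m (n x k)
  int colbc(int v, int m) {
    arma::mat out = nodes[m].val;
    out.each_row() %= arma::rowvec(nodes[v].val.col(0).t());
    return make(COLBC, v, m, std::move(out));
  }
  // v (n x 1) added to every column of m (n x k)
  int rowadd(int v, int m) {
    arma::mat out = nodes[m].val;
    out.each_col() += arma::vec(nodes[v].val.col(0));
    return make(ROWADD, v, m, std::move(out));
  }
  int vcat2(int a, int b) {
    return make(VCAT2, a, b, arma::join_cols(nodes[a].val, nodes[b].val));
  }
  int vcat3(int a, int b, int c3) {
    int ab = vcat2(a, b);
    int id = make(VCAT3, ab, c3, arma::join_cols(nodes[ab].val, nodes[c3].val));
    return id;
  }
  // rows r0..r1 (inclusive, 0-based) of a column vector / matrix
  int rowsel(int a, int r0, int r1) {
    int id = make(ROWSEL, a, -1, nodes[a].val.rows(r0, r1));
    nodes[id].i0 = r0; nodes[id].i1 = r1; return id;
  }
  // single column j0 (0-based) of a matrix
  int colsel(int a, int j0) {
    int id = make(COLSEL, a, -1, nodes[a].val.col(j0));
    nodes[id].i0 = j0; return id;
  }
  int sigmoid(int a) {
    return make(SIGMOID, a, -1, 1.0 / (1.0 + arma::exp(-nodes[a].val)));
  }
  int expop(int a) { return make(EXPOP, a, -1, arma::exp(nodes[a].val)); }
  int relu(int a) {
    return make(RELU, a, -1, arma::clamp(nodes[a].val, 0.0, arma::datum::inf));
  }
  int softplus(int a) {
    const arma::mat& x = nodes[a].val;
    arma::mat out = arma::clamp(x, 0.0, arma::datum::inf) +
      arma::log1p(arma::exp(-arma::abs(x)));
    return make(SOFTPLUS, a, -1, std::move(out));
  }
  // Heaviside forward, surrogate backward.  shape: 0 = exp, 1 = fast sigmoid.
  int spike(int v, double v_th, int shape, double scale, double amplitude) {
    const arma::mat& x = nodes[v].val;
    arma::mat s = arma::conv_to<arma::mat>::from(x > v_th);
    arma::mat d = arma::abs(x - v_th);
    arma::mat g = (shape == 0) ? arma::mat(amplitude * arma::exp(-scale * d))
                               : arma::mat(amplitude / arma::square(1.0 + scale * d));
    int id = make(SPIKE, v, -1, std::move(s));
    nodes[id].aux = std::move(g);
    return id;
  }
  int sumall(int a) {
    arma::mat out(1, 1); out(0, 0) = arma::accu(nodes[a].val);
    return make(SUMALL, a, -1, std::move(out));
  }
  int logsumexp(int a) {
    const arma::vec z = nodes[a].val.col(0);
    double m = z.max();
    arma::vec e = arma::exp(z - m);
    double s = arma::accu(e);
    arma::mat out(1, 1); out(0, 0) = m + std::log(s);
    int id = make(LOGSUMEXP, a, -1, std::move(out));
    nodes[id].aux = e / s;
    return id;
  }
  int pick(int a, int idx0) {
    arma::mat out(1, 1); out(0, 0) = nodes[a].val(idx0, 0);
    int id = make(PICK, a, -1, std::move(out));
    nodes[id].i0 = idx0; return id;
  }
  // elementwise product with a constant matrix
  int mulcm(int a, const arma::mat& cmat) {
    int id = make(MULCM, a, -1, nodes[a].val % cmat);
    nodes[id].aux = cmat; return id;
  }
  // val(i,j) = a_flat(idx(i,j) - 1); idx == 0 means structural zero (padding)
  int gather(int a, const arma::umat& idx) {
    const arma::mat& x = nodes[a].val;
    arma::mat out(idx.n_rows, idx.n_cols, arma::fill::zeros);
    for (arma::uword j = 0; j < idx.n_cols; ++j)
      for (arma::uword i = 0; i < idx.n_rows; ++i)
        if (idx(i, j) > 0) out(i, j) = x(idx(i, j) - 1);
    int id = make(GATHER, a, -1, std::move(out));
    nodes[id].aux = arma::conv_to<arma::mat>::from(idx);
    return id;
  }
  // max-pool over columns: cand (k x n_out) holds 1-based column indices of a
  int pool(int a, const arma::umat& cand) {
    const arma::mat& x = nodes[a].val;
    arma::mat out(x.n_rows, cand.n_cols);
    arma::mat arg(x.n_rows, cand.n_cols);
    for (arma::uword j = 0; j < cand.n_cols; ++j) {
      for (arma::uword r = 0; r < x.n_rows; ++r) {
        double best = -arma::datum::inf; arma::uword bi = 0;
        for (arma::uword k = 0; k < cand.n_rows; ++k) {
          double v = x(r, cand(k, j) - 1);
          if (v > best) { best = v; bi = cand(k, j) - 1; }
        }
        out(r, j) = best; arg(r, j) = static_cast<double>(bi);
      }
    }
    int id = make(POOL, a, -1, std::move(out));
    nodes[id].aux = std::move(arg);
    return id;
  }
  // per-row standardization over columns (instance-norm core)
  int rownorm(int a, double eps = 1e-5) {
    const arma::mat& x = nodes[a].val;
    arma::vec mu = arma::mean(x, 1);
    arma::vec sd = arma::sqrt(arma::var(x, 1, 1) + eps);  // population variance
    arma::mat z = x;
    z.each_col() -= mu;
    z.each_col() /= sd;
    int id = make(ROWNORM, a, -1, std::move(z));
    nodes[id].aux = sd;
    return id;
  }
  int reshape(int a, arma::uword r, arma::uword c) {
    int id = make(RESHAPE, a, -1, arma::reshape(nodes[a].val, r, c));
    return id;
  }

  void addg(int id, const arma::mat& g) {
    if (id < 0 || !nodes[id].needs) return;
    if (nodes[id].grad.n_elem == 0) nodes[id].grad = g;
    else nodes[id].grad += g;
  }

  const arma::mat& grad_of(int id) {
    static arma::mat empty;
    if (nodes[id].grad.n_elem == 0) {
      nodes[id].grad = arma::zeros(nodes[id].val.n_rows, nodes[id].val.n_cols);
    }
    return nodes[id].grad;
  }

  void backward(int loss_id) {
    nodes[loss_id].grad = arma::ones(1, 1);
    for (int i = loss_id; i >= 0; --i) {
      Node& nd = nodes[i];
      if (!nd.needs || nd.grad.n_elem == 0) continue;
      const arma::mat& g = nd.grad;
      switch (nd.op) {
        case LEAF: break;
        case ADD: addg(nd.a, g); addg(nd.b, g); break;
        case SUB: addg(nd.a, g); if (needs(nd.b)) addg(nd.b, -g); break;
        case EMUL:
          if (needs(nd.a)) addg(nd.a, g % nodes[nd.b].val);
          if (needs(nd.b)) addg(nd.b, g % nodes[nd.a].val);
          break;
        case MATMUL:
          if (needs(nd.a)) addg(nd.a, g * nodes[nd.b].val.t());
          if (needs(nd.b)) addg(nd.b, nodes[nd.a].val.t() * g);
          break;
        case OUTER:
          if (needs(nd.a)) addg(nd.a, g * nodes[nd.b].val);
          if (needs(nd.b)) addg(nd.b, g.t() * nodes[nd.a].val);
          break;
        case SMUL: addg(nd.a, nd.c * g); break;
        case ADDC: addg(nd.a, g); break;
        case BMUL:
          if (needs(nd.a)) {
            arma::mat gs(1, 1); gs(0, 0) = arma::accu(g % nodes[nd.b].val);
            addg(nd.a, gs);
          }
          if (needs(nd.b)) addg(nd.b, nodes[nd.a].val(0, 0) * g);
          break;
        case BADD:
          if (needs(nd.a)) {
            arma::mat gs(1, 1); gs(0, 0) = arma::accu(g);
            addg(nd.a, gs);
          }
          addg(nd.b, g);
          break;
        case ROWBC:
          if (needs(nd.a)) addg(nd.a, arma::sum(g % nodes[nd.b].val, 1));
          if (needs(nd.b)) {
            arma::mat gb = g;
            gb.each_col() %= arma::vec(nodes[nd.a].val.col(0));
            addg(nd.b, gb);
          }
          break;
        case COLBC:
          if (needs(nd.a)) addg(nd.a, arma::sum(g % nodes[nd.b].val, 0).t());
          if (needs(nd.b)) {
            arma::mat gb = g;
            gb.each_row() %= arma::rowvec(nodes[nd.a].val.col(0).t());
            addg(nd.b, gb);
          }
          break;
        case ROWADD:
          if (needs(nd.a)) addg(nd.a, arma::sum(g, 1));
          addg(nd.b, g);
          break;
        case VCAT2: case VCAT3: {
          arma::uword na = nodes[nd.a].val.n_rows;
          if (needs(nd.a)) addg(nd.a, g.rows(0, na - 1));
          if (needs(nd.b)) addg(nd.b, g.rows(na, g.n_rows - 1));
          break;
        }
        case ROWSEL: {
          if (needs(nd.a)) {
            arma::mat ga = arma::zeros(nodes[nd.a].val.n_rows,
                                       nodes[nd.a].val.n_cols);
            ga.rows(nd.i0, nd.i1) = g;
            addg(nd.a, ga);
          }
          break;
        }
        case COLSEL: {
          if (needs(nd.a)) {
            arma::mat ga = arma::zeros(nodes[nd.a].val.n_rows,
                                       nodes[nd.a].val.n_cols);
            ga.col(nd.i0) = g;
            addg(nd.a, ga);
          }
          break;
        }
        case SIGMOID: addg(nd.a, g % nd.val % (1.0 - nd.val)); break;
        case EXPOP: addg(nd.a, g % nd.val); break;
        case RELU:
          addg(nd.a, g % arma::conv_to<arma::mat>::from(nodes[nd.a].val > 0));
          break;
        case SOFTPLUS:
          addg(nd.a, g % (1.0 / (1.0 + arma::exp(-nodes[nd.a].val))));
          break;
        case SPIKE: addg(nd.a, g % nd.aux); break;
        case SUMALL:
          addg(nd.a, g(0, 0) * arma::ones(nodes[nd.a].val.n_rows,
                                          nodes[nd.a].val.n_cols));
          break;
        case LOGSUMEXP: addg(nd.a, g(0, 0) * nd.aux); break;
        case PICK: {
          if (needs(nd.a)) {
            arma::mat ga = arma::zeros(nodes[nd.a].val.n_rows, 1);
            ga(nd.i0, 0) = g(0, 0);
            addg(nd.a, ga);
          }
          break;
        }
        case MULCM: addg(nd.a, g % nd.aux); break;
        case GATHER: {
          if (needs(nd.a)) {
            arma::mat ga = arma::zeros(nodes[nd.a].val.n_rows,
                                       nodes[nd.a].val.n_cols);
            double* gp = ga.memptr();
            for (arma::uword j = 0; j < nd.aux.n_cols; ++j)
              for (arma::uword i = 0; i < nd.aux.n_rows; ++i) {
                arma::uword idx = static_cast<arma::uword>(nd.aux(i, j));
                if (idx > 0) gp[idx - 1] += g(i, j);
              }
            addg(nd.a, ga);
          }
          break;
        }
        case POOL: {
          if (needs(nd.a)) {
            arma::mat ga = arma::zeros(nodes[nd.a].val.n_rows,
                                       nodes[nd.a].val.n_cols);
            for (arma::uword j = 0; j < nd.aux.n_cols; ++j)
              for (arma::uword r = 0; r < nd.aux.n_rows; ++r)
                ga(r, static_cast<arma::uword>(nd.aux(r, j))) += g(r, j);
            addg(nd.a, ga);
          }
          break;
        }
        case ROWNORM: {
          if (needs(nd.a)) {
            arma::uword m = nd.val.n_cols;
            arma::vec gmean = arma::sum(g, 1) / double(m);
            arma::vec gzmean = arma::sum(g % nd.val, 1) / double(m);
            arma::mat ga = g;
            ga.each_col() -= gmean;
            ga -= nd.val.each_col() % gzmean;
            ga.each_col() /= arma::vec(nd.aux.col(0));
            addg(nd.a, ga);
          }
          break;
        }
        case RESHAPE:
          if (needs(nd.a)) {
            addg(nd.a, arma::reshape(g, nodes[nd.a].val.n_rows,
                                     nodes[nd.a].val.n_cols));
          }
          break;
      }
      // free as we go (parents already received their share); leaf gradients
      // are the caller's payload and must survive the sweep
      if (nd.op != LEAF) nd.grad.reset();
    }
  }
};

// Neuron/surrogate constants shared by the simulators.
struct CubaCfg {
  double alpha_u, alpha_v, u_rest, v_rest, R, v_th;
  bool post_update_u;
  int surr_shape;
  double surr_scale, surr_amp;
};

// One CUBA LIF step on the tape.  u and v are node ids, updated in place;
// returns the spike node.  Reset is a hard reset to v_rest applied after
// spike readout, with gradients flowing through the surrogate.
inline int cuba_step(Tape& tp, int& u, int& v, int I, const CubaCfg& p) {
  int u_new = tp.addc(tp.add(tp.smul(u, 1.0 - p.alpha_u), I),
                      p.alpha_u * p.u_rest);
  int u_for_v = p.post_update_u ? u_new : u;
  int v_pre = tp.addc(tp.add(tp.smul(v, 1.0 - p.alpha_v),
                             tp.smul(u_for_v, p.R)),
                      p.alpha_v * p.v_rest);
  int s = tp.spike(v_pre, p.v_th, p.surr_shape, p.surr_scale, p.surr_amp);
  int om_s = tp.addc(tp.smul(s, -1.0), 1.0);
  int v_after = tp.emul(v_pre, om_s);
  if (p.v_rest != 0.0) v_after = tp.add(v_after, tp.smul(s, p.v_rest));
  u = u_new;
  v = v_after;
  return s;
}

}  // namespace mspk

#endif
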