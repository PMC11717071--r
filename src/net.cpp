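// Stacked bidirectional LSTM with additive attention pooling and a dense
// head, mapping a spectrum (ordered wavelength sequence, one reflectance
// value per step) to a scalar. Forward pass and full backpropagation
// through time; parameters travel as a named R list of matrices so the R
// side owns initialization and the optimizer.
//
// Gate order within the 4h-wide concatenated blocks: input, forget,
// output, candidate (i, f, o, g).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LstmCache {
  cube I, F, O, G, C, H;  // each n x h x T, indexed by true time t
};

// Xin: n x d x T. reverse=false processes t = 0..T-1, reverse=true T-1..0.
static void lstm_forward(const cube& Xin, const mat& W, const mat& U,
                         const mat& b, bool reverse, LstmCache& cc) {
  const arma::uword n = Xin.n_rows, d = Xin.n_cols, T = Xin.n_slices;
  const arma::uword h = U.n_rows;
  cc.I.set_size(n, h, T); cc.F.set_size(n, h, T); cc.O.set_size(n, h, T);
  cc.G.set_size(n, h, T); cc.C.set_size(n, h, T); cc.H.set_size(n, h, T);
  // input projection for every step in one gemm over the stacked slices
  mat Xstack(n * T, d);
  for (arma::uword t = 0; t < T; ++t)
    Xstack.rows(t * n, (t + 1) * n - 1) = Xin.slice(t);
  mat AX = Xstack * W;              // (n*T) x 4h
  AX.each_row() += b.row(0);
  mat hprev(n, h, arma::fill::zeros), cprev(n, h, arma::fill::zeros);
  mat A(n, 4 * h);
  const arma::uword nh = n * h;
  for (arma::uword k = 0; k < T; ++k) {
    arma::uword t = reverse ? (T - 1 - k) : k;
    A = AX.rows(t * n, (t + 1) * n - 1);
    A += hprev * U;
    // fused gate pass: one loop computes all activations and the state
    double* ip = cc.I.slice_memptr(t); double* fp = cc.F.slice_memptr(t);
    double* op = cc.O.slice_memptr(t); double* gp = cc.G.slice_memptr(t);
    double* cp = cc.C.slice_memptr(t); double* hp = cc.H.slice_memptr(t);
    const double* ap = A.memptr();
    const double* cprevp = cprev.memptr();
    for (arma::uword j = 0; j < nh; ++j) {
      double i = 1.0 / (1.0 + std::exp(-ap[j]));
      double f = 1.0 / (1.0 + std::exp(-ap[j + nh]));
      double o = 1.0 / (1.0 + std::exp(-ap[j + 2 * nh]));
      double g = std::tanh(ap[j + 3 * nh]);
      double c = f * cprevp[j] + i * g;
      ip[j] = i; fp[j] = f; op[j] = o; gp[j] = g;
      cp[j] = c; hp[j] = o * std::tanh(c);
    }
    hprev = cc.H.slice(t); cprev = cc.C.slice(t);
  }
}

// dH_ext: upstream gradient w.r.t. H at every step. Returns dX via out
// parameter and accumulates dW, dU, db (caller supplies zeroed matrices).
static void lstm_backward(const cube& Xin, const mat& W, const mat& U,
                          bool reverse, const LstmCache& cc,
                          const cube& dH_ext, cube& dX, mat& dW, mat& dU,
                          mat& db) {
  const arma::uword n = Xin.n_rows, d = Xin.n_cols, T = Xin.n_slices;
  const arma::uword h = U.n_rows;
  cube dAcube(n, 4 * h, T);
  const mat zero(n, h, arma::fill::zeros);
  mat dh_carry(n, h, arma::fill::zeros), dc_carry(n, h, arma::fill::zeros);
  const arma::uword nh = n * h;
  for (arma::uword k = 0; k < T; ++k) {
    // walk the processing order backwards
    arma::uword kk = T - 1 - k;
    arma::uword t = reverse ? (T - 1 - kk) : kk;
    // previous state in processing order
    bool first = (kk == 0);
    arma::uword tprev = reverse ? (t + 1) : (t - 1);  // only if !first
    const mat& hprev = first ? zero : cc.H.slice(tprev);
    const mat& cprev = first ? zero : cc.C.slice(tprev);

    // fused backward gate pass
    mat& dA = dAcube.slice(t);
    const double* ip = cc.I.slice_memptr(t);
    const double* fp = cc.F.slice_memptr(t);
    const double* op = cc.O.slice_memptr(t);
    const double* gp = cc.G.slice_memptr(t);
    const double* cp = cc.C.slice_memptr(t);
    const double* cprevp = cprev.memptr();
    const double* dhe = dH_ext.slice_memptr(t);
    double* dhc = dh_carry.memptr();
    double* dcc = dc_carry.memptr();
    double* dap = dA.memptr();
    for (arma::uword j = 0; j < nh; ++j) {
      double i = ip[j], f = fp[j], o = op[j], g = gp[j];
      double tc = std::tanh(cp[j]);
      double dh = dhe[j] + dhc[j];
      double do_ = dh * tc;
      double dc = dcc[j] + dh * o * (1.0 - tc * tc);
      dap[j]          = (dc * g) * i * (1.0 - i);
      dap[j + nh]     = (dc * cprevp[j]) * f * (1.0 - f);
      dap[j + 2 * nh] = do_ * o * (1.0 - o);
      dap[j + 3 * nh] = (dc * i) * (1.0 - g * g);
      dcc[j] = dc * f;
    }

    dU += hprev.t() * dA;
    dh_carry = dA * U.t();
  }
  // input-side gradients in single gemms over the stacked step slices
  mat Xstack(n * T, d), dAstack(n * T, 4 * h);
  for (arma::uword t = 0; t < T; ++t) {
    Xstack.rows(t * n, (t + 1) * n - 1) = Xin.slice(t);
    dAstack.rows(t * n, (t + 1) * n - 1) = dAcube.slice(t);
  }
  dW += Xstack.t() * dAstack;
  db.row(0) += arma::sum(dAstack, 0);
  mat dXstack = dAstack * W.t();               // (n*T) x d
  dX.set_size(n, d, T);
  for (arma::uword t = 0; t < T; ++t)
    dX.slice(t) = dXstack.rows(t * n, (t + 1) * n - 1);
}

struct NetCaches {
  LstmCache l1f, l1b, l2f, l2b;
  cube Z1;        // layer-2 input, n x d2 x T
  cube S;         // merged per-step state, n x m x T
  cube Uatt;      // attention tanh projection, n x attn x T
  mat alpha;      // n x T attention weights
  mat ctx;        // n x m context
  mat dvec;       // n x dense
  vec pred;       // n
};

static void net_forward_full(const List& par, const mat& X, bool bidir,
                             bool attention, NetCaches& nc) {
  const arma::uword n = X.n_rows, T = X.n_cols;
  mat l1f_W = par["l1f_W"], l1f_U = par["l1f_U"], l1f_b = par["l1f_b"];
  mat l2f_W = par["l2f_W"], l2f_U = par["l2f_U"], l2f_b = par["l2f_b"];
  mat m_Wf = par["m_Wf"], m_b = par["m_b"];
  mat a_W = par["a_W"], a_b = par["a_b"], a_v = par["a_v"];
  mat d_W = par["d_W"], d_b = par["d_b"];
  mat o_w = par["o_w"], o_b = par["o_b"];
  const arma::uword h1 = l1f_U.n_rows, m = m_Wf.n_cols;

  cube Xseq(n, 1, T);
  for (arma::uword t = 0; t < T; ++t) Xseq.slice(t) = X.col(t);

  lstm_forward(Xseq, l1f_W, l1f_U, l1f_b, false, nc.l1f);
  if (bidir) {
    mat l1b_W = par["l1b_W"], l1b_U = par["l1b_U"], l1b_b = par["l1b_b"];
    lstm_forward(Xseq, l1b_W, l1b_U, l1b_b, true, nc.l1b);
  }

  const arma::uword d2 = bidir ? 2 * h1 : h1;
  nc.Z1.set_size(n, d2, T);
  for (arma::uword t = 0; t < T; ++t) {
    nc.Z1.slice(t).cols(0, h1 - 1) = nc.l1f.H.slice(t);
    if (bidir) nc.Z1.slice(t).cols(h1, 2 * h1 - 1) = nc.l1b.H.slice(t);
  }

  lstm_forward(nc.Z1, l2f_W, l2f_U, l2f_b, false, nc.l2f);
  if (bidir) {
    mat l2b_W = par["l2b_W"], l2b_U = par["l2b_U"], l2b_b = par["l2b_b"];
    lstm_forward(nc.Z1, l2b_W, l2b_U, l2b_b, true, nc.l2b);
  }

  // tanh-weighted merge of the directional streams at every step
  nc.S.set_size(n, m, T);
  mat m_Wb;
  if (bidir) m_Wb = as<mat>(par["m_Wb"]);
  for (arma::uword t = 0; t < T; ++t) {
    mat pre = nc.l2f.H.slice(t) * m_Wf;
    if (bidir) pre += nc.l2b.H.slice(t) * m_Wb;
    pre.each_row() += m_b.row(0);
    nc.S.slice(t) = arma::tanh(pre);
  }

  // attention pooling over steps (uniform mean pooling when disabled)
  nc.alpha.set_size(n, T);
  if (attention) {
    const arma::uword attn = a_W.n_cols;
    nc.Uatt.set_size(n, attn, T);
    mat E(n, T);
    for (arma::uword t = 0; t < T; ++t) {
      mat u = nc.S.slice(t) * a_W;
      u.each_row() += a_b.row(0);
      u = arma::tanh(u);
      nc.Uatt.slice(t) = u;
      E.col(t) = u * a_v;
    }
    E.each_col() -= arma::max(E, 1);
    mat ex = arma::exp(E);
    nc.alpha = ex.each_col() / arma::sum(ex, 1);
  } else {
    nc.alpha.fill(1.0 / double(T));
  }
  nc.ctx.set_size(n, m); nc.ctx.zeros();
  for (arma::uword t = 0; t < T; ++t)
    nc.ctx += nc.S.slice(t).each_col() % nc.alpha.col(t);

  mat dpre = nc.ctx * d_W;
  dpre.each_row() += d_b.row(0);
  nc.dvec = arma::tanh(dpre);
  nc.pred = nc.dvec * arma::vectorise(o_w) + o_b(0, 0);
}

// [[Rcpp::export]]
List cpp_net_forward(List par, arma::mat X, bool bidir, bool attention) {
  NetCaches nc;
  net_forward_full(par, X, bidir, attention, nc);
  return List::create(_["pred"] = NumericVector(nc.pred.begin(),
                                                nc.pred.end()),
                      _["attention"] = wrap(nc.alpha));
}

// [[Rcpp::export]]
List cpp_net_loss_grad(List par, arma::mat X, arma::vec y, bool bidir,
                       bool attention) {
  NetCaches nc;
  net_forward_full(par, X, bidir, attention, nc);
  const arma::uword n = X.n_rows, T = X.n_cols;

  vec resid = nc.pred - y;
  double loss = arma::dot(resid, resid) / double(n);
  vec dpred = 2.0 * resid / double(n);

  mat m_Wf = par["m_Wf"];
  mat a_W = par["a_W"], a_v = par["a_v"];
  mat d_W = par["d_W"];
  mat o_w = par["o_w"];
  mat l1f_W = par["l1f_W"], l1f_U = par["l1f_U"];
  mat l2f_W = par["l2f_W"], l2f_U = par["l2f_U"];
  const arma::uword m = m_Wf.n_cols;
  const arma::uword h1 = l1f_U.n_rows;

  // output + dense head
  mat d_o_w = nc.dvec.t() * dpred;                       // dense x 1
  mat d_o_b(1, 1); d_o_b(0, 0) = arma::accu(dpred);
  mat dd = dpred * arma::vectorise(o_w).t();             // n x dense
  mat dpre_d = dd % (1.0 - nc.dvec % nc.dvec);
  mat d_d_W = nc.ctx.t() * dpre_d;
  mat d_d_b = arma::sum(dpre_d, 0);
  mat dctx = dpre_d * d_W.t();                           // n x m

  // attention / pooling backward into per-step merged states
  cube dS(n, m, T, arma::fill::zeros);
  mat d_a_W, d_a_b, d_a_v;
  if (attention) {
    const arma::uword attn = a_W.n_cols;
    d_a_W.zeros(m, attn); d_a_b.zeros(1, attn); d_a_v.zeros(attn, 1);
    mat dalpha(n, T);
    for (arma::uword t = 0; t < T; ++t) {
      dS.slice(t) = dctx.each_col() % nc.alpha.col(t);
      dalpha.col(t) = arma::sum(dctx % nc.S.slice(t), 1);
    }
    vec row_dot = arma::sum(nc.alpha % dalpha, 1);
    mat dE = nc.alpha % (dalpha.each_col() - row_dot);
    for (arma::uword t = 0; t < T; ++t) {
      mat u = nc.Uatt.slice(t);
      d_a_v += u.t() * dE.col(t);
      mat du = dE.col(t) * arma::vectorise(a_v).t();     // n x attn
      mat dpre_u = du % (1.0 - u % u);
      d_a_W += nc.S.slice(t).t() * dpre_u;
      d_a_b.row(0) += arma::sum(dpre_u, 0);
      dS.slice(t) += dpre_u * a_W.t();
    }
  } else {
    d_a_W.zeros(arma::size(as<mat>(par["a_W"])));
    d_a_b.zeros(arma::size(as<mat>(par["a_b"])));
    d_a_v.zeros(arma::size(as<mat>(par["a_v"])));
    for (arma::uword t = 0; t < T; ++t)
      dS.slice(t) = dctx / double(T);
  }

  // merge backward
  const arma::uword h2 = l2f_U.n_rows;
  mat d_m_Wf(h2, m, arma::fill::zeros), d_m_Wb, d_m_b(1, m,
                                                      arma::fill::zeros);
  cube dH2f(n, h2, T, arma::fill::zeros), dH2b;
  mat m_Wb;
  if (bidir) {
    m_Wb = as<mat>(par["m_Wb"]);
    d_m_Wb.zeros(h2, m);
    dH2b.zeros(n, h2, T);
  }
  for (arma::uword t = 0; t < T; ++t) {
    mat s = nc.S.slice(t);
    mat dpre_s = dS.slice(t) % (1.0 - s % s);
    d_m_Wf += nc.l2f.H.slice(t).t() * dpre_s;
    d_m_b.row(0) += arma::sum(dpre_s, 0);
    dH2f.slice(t) = dpre_s * m_Wf.t();
    if (bidir) {
      d_m_Wb += nc.l2b.H.slice(t).t() * dpre_s;
      dH2b.slice(t) = dpre_s * m_Wb.t();
    }
  }

  // layer-2 LSTMs backward
  mat d_l2f_W(arma::size(l2f_W), arma::fill::zeros),
      d_l2f_U(arma::size(l2f_U), arma::fill::zeros),
      d_l2f_b(1, 4 * h2, arma::fill::zeros);
  cube dZ1;
  lstm_backward(nc.Z1, l2f_W, l2f_U, false, nc.l2f, dH2f, dZ1, d_l2f_W,
                d_l2f_U, d_l2f_b);
  mat d_l2b_W, d_l2b_U, d_l2b_b;
  if (bidir) {
    mat l2b_W = par["l2b_W"], l2b_U = par["l2b_U"];
    d_l2b_W.zeros(arma::size(l2b_W));
    d_l2b_U.zeros(arma::size(l2b_U));
    d_l2b_b.zeros(1, 4 * h2);
    cube dZ1b;
    lstm_backward(nc.Z1, l2b_W, l2b_U, true, nc.l2b, dH2b, dZ1b, d_l2b_W,
                  d_l2b_U, d_l2b_b);
    dZ1 += dZ1b;
  }

  // split layer-2 input gradient back onto the layer-1 streams
  cube dH1f(n, h1, T), dH1b;
  for (arma::uword t = 0; t < T; ++t)
    dH1f.slice(t) = dZ1.slice(t).cols(0, h1 - 1);
  if (bidir) {
    dH1b.set_size(n, h1, T);
    for (arma::uword t = 0; t < T; ++t)
      dH1b.slice(t) = dZ1.slice(t).cols(h1, 2 * h1 - 1);
  }

  cube Xseq(n, 1, T);
  for (arma::uword t = 0; t < T; ++t) Xseq.slice(t) = X.col(t);
  mat d_l1f_W(arma::size(l1f_W), arma::fill::zeros),
      d_l1f_U(arma::size(l1f_U), arma::fill::zeros),
      d_l1f_b(1, 4 * h1, arma::fill::zeros);
  cube dX_unused;
  lstm_backward(Xseq, l1f_W, l1f_U, false, nc.l1f, dH1f, dX_unused,
                d_l1f_W, d_l1f_U, d_l1f_b);
  mat d_l1b_W, d_l1b_U, d_l1b_b;
  if (bidir) {
    mat l1b_W = par["l1b_W"], l1b_U = par["l1b_U"];
    d_l1b_W.zeros(arma::size(l1b_W));
    d_l1b_U.zeros(arma::size(l1b_U));
    d_l1b_b.zeros(1, 4 * h1);
    cube dXb;
    lstm_backward(Xseq, l1b_W, l1b_U, true, nc.l1b, dH1b, dXb, d_l1b_W,
                  d_l1b_U, d_l1b_b);
  }

  List grads = List::create(
    _["l1f_W"] = d_l1f_W, _["l1f_U"] = d_l1f_U, _["l1f_b"] = d_l1f_b,
    _["l2f_W"] = d_l2f_W, _["l2f_U"] = d_l2f_U, _["l2f_b"] = d_l2f_b,
    _["m_Wf"] = d_m_Wf, _["m_b"] = d_m_b,
    _["a_W"] = d_a_W, _["a_b"] = d_a_b, _["a_v"] = d_a_v,
    _["d_W"] = d_d_W, _["d_b"] = d_d_b,
    _["o_w"] = d_o_w, _["o_b"] = d_o_b);
  if (bidir) {
    grads["l1b_W"] = d_l1b_W; grads["l1b_U"] = d_l1b_U;
    grads["l1b_b"] = d_l1b_b;
    grads["l2b_W"] = d_l2b_W; grads["l2b_U"] = d_l2b_U;
    grads["l2b_b"] = d_l2b_b;
    grads["m_Wb"] = d_m_Wb;
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// Full minibatch-Adam training loop. X, y are already on the standardized
// target scale; the batch order uses R's RNG so runs are reproducible
// under set.seed(). Returns the trained parameters and per-epoch MSEs.
// [[Rcpp::export]]
List cpp_net_train(List par, arma::mat X, arma::vec y, arma::mat Xval,
                   arma::vec yval, int num_epochs, int batch_size,
                   double lr, bool bidir, bool attention) {
  const int n = X.n_rows;
  const bool has_val = Xval.n_rows > 0;
  CharacterVector nms = par.names();
  const int np = nms.size();
  std::vector<mat> P(np), M(np), V(np);
  for (int j = 0; j < np; ++j) {
    P[j] = as<mat>(par[j]);
    M[j].zeros(arma::size(P[j]));
    V[j].zeros(arma::size(P[j]));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  NumericVector hist_train(num_epochs), hist_val(num_epochs);
  List parw(par);  // working list handed to the forward/backward core
  int bs = std::min(batch_size, n);

  for (int ep = 0; ep < num_epochs; ++ep) {
    IntegerVector ord = Rcpp::sample(n, n, false);  // R RNG, 1-based
    double ep_loss = 0; int ep_n = 0;
    for (int start = 0; start < n; start += bs) {
      int len = std::min(bs, n - start);
      arma::uvec idx(len);
      for (int k = 0; k < len; ++k) idx[k] = ord[start + k] - 1;
      for (int j = 0; j < np; ++j) parw[j] = P[j];
      List lg = cpp_net_loss_grad(parw, X.rows(idx), y.elem(idx), bidir,
                                  attention);
      double loss = as<double>(lg["loss"]);
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss); reduce the learning rate");
      ep_loss += loss * len; ep_n += len;
      List grads = lg["grads"];
      ++step;
      double c1 = 1.0 - std::pow(b1, double(step));
      double c2 = 1.0 - std::pow(b2, double(step));
      for (int j = 0; j < np; ++j) {
        mat g = as<mat>(grads[std::string(nms[j])]);
        M[j] = b1 * M[j] + (1 - b1) * g;
        V[j] = b2 * V[j] + (1 - b2) * (g % g);
        P[j] -= lr * (M[j] / c1) / (arma::sqrt(V[j] / c2) + eps);
      }
    }
    hist_train[ep] = ep_loss / ep_n;
    if (has_val) {
      for (int j = 0; j < np; ++j) parw[j] = P[j];
      NetCaches nc;
      net_forward_full(parw, Xval, bidir, attention, nc);
      hist_val[ep] = arma::mean(arma::square(nc.pred - yval));
    }
  }
  List out_par(np);
  for (int j = 0; j < np; ++j) out_par[j] = P[j];
  out_par.names() = nms;
  return List::create(_["parameters"] = out_par,
                      _["train_mse"] = hist_train,
                      _["val_mse"] = hist_val);
}
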