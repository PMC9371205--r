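// Stacked bidirectional LSTM classifier: forward pass, backpropagation
// through time, ADAM updates, inverted dropout / recurrent dropout, and
// batch normalization on the dense head. The network is small (sequence
// length = 6 in the default layout) so everything is dense arma::mat work.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <vector>
#include <string>

using namespace arma;

static const double BN_EPS = 1e-3;    // matches common DL framework default
static const double ADAM_EPS = 1e-7;
static const double BN_MOMENTUM = 0.99;

struct LstmDir {
  mat W, U;  // d x 4u, u x 4u (gate order i, f, g, o)
  rowvec b;  // 4u
};

struct Layer {
  LstmDir fwd, bwd;
  unsigned u;
};

struct Net {
  std::vector<Layer> layers;
  mat W1;            // dIn x 50
  rowvec b1;         // 50
  rowvec gamma, beta, rmean, rvar;
  mat W2;            // 50 x 8
  rowvec b2;
};

static Net parse_net(const Rcpp::List& w) {
  Net net;
  int nl = Rcpp::as<int>(w["n_layers"]);
  Rcpp::List ll = w["layers"];
  for (int l = 0; l < nl; ++l) {
    Rcpp::List L = ll[l];
    Layer lay;
    lay.fwd.W = Rcpp::as<mat>(L["Wf"]);
    lay.fwd.U = Rcpp::as<mat>(L["Uf"]);
    lay.fwd.b = Rcpp::as<rowvec>(L["bf"]);
    lay.bwd.W = Rcpp::as<mat>(L["Wb"]);
    lay.bwd.U = Rcpp::as<mat>(L["Ub"]);
    lay.bwd.b = Rcpp::as<rowvec>(L["bb"]);
    lay.u = lay.fwd.U.n_rows;
    net.layers.push_back(lay);
  }
  net.W1 = Rcpp::as<mat>(w["W1"]);
  net.b1 = Rcpp::as<rowvec>(w["b1"]);
  net.gamma = Rcpp::as<rowvec>(w["gamma"]);
  net.beta = Rcpp::as<rowvec>(w["beta"]);
  net.rmean = Rcpp::as<rowvec>(w["rmean"]);
  net.rvar = Rcpp::as<rowvec>(w["rvar"]);
  net.W2 = Rcpp::as<mat>(w["W2"]);
  net.b2 = Rcpp::as<rowvec>(w["b2"]);
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List ll(net.layers.size());
  for (size_t l = 0; l < net.layers.size(); ++l) {
    const Layer& L = net.layers[l];
    ll[l] = Rcpp::List::create(
      Rcpp::Named("Wf") = L.fwd.W, Rcpp::Named("Uf") = L.fwd.U,
      Rcpp::Named("bf") = L.fwd.b, Rcpp::Named("Wb") = L.bwd.W,
      Rcpp::Named("Ub") = L.bwd.U, Rcpp::Named("bb") = L.bwd.b);
  }
  return Rcpp::List::create(
    Rcpp::Named("n_layers") = (int)net.layers.size(),
    Rcpp::Named("layers") = ll,
    Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
    Rcpp::Named("gamma") = net.gamma, Rcpp::Named("beta") = net.beta,
    Rcpp::Named("rmean") = net.rmean, Rcpp::Named("rvar") = net.rvar,
    Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2);
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---- single-direction LSTM scan with caches for BPTT -------------------
struct DirCache {
  std::vector<mat> i, f, g, o, c, tc, hprev, ain; // per scan position
  std::vector<mat> h;
};

// steps: order in which this direction consumes the sequence
static void lstm_scan(const LstmDir& d, const std::vector<mat>& xseq,
                      const std::vector<int>& steps, const mat& min,
                      const mat& mrec, bool use_masks, DirCache& cc) {
  unsigned u = d.U.n_rows;
  unsigned B = xseq[0].n_rows;
  size_t T = steps.size();
  cc.i.resize(T); cc.f.resize(T); cc.g.resize(T); cc.o.resize(T);
  cc.c.resize(T); cc.tc.resize(T); cc.hprev.resize(T); cc.ain.resize(T);
  cc.h.resize(T);
  mat h(B, u, fill::zeros), c(B, u, fill::zeros);
  for (size_t k = 0; k < T; ++k) {
    const mat& x = xseq[steps[k]];
    mat a = use_masks ? mat(x % min) : x;
    mat hin = use_masks ? mat(h % mrec) : h;
    mat z = a * d.W + hin * d.U;
    z.each_row() += d.b;
    mat zi = sigm(z.cols(0, u - 1));
    mat zf = sigm(z.cols(u, 2 * u - 1));
    mat zg = tanh(z.cols(2 * u, 3 * u - 1));
    mat zo = sigm(z.cols(3 * u, 4 * u - 1));
    cc.hprev[k] = h;
    cc.ain[k] = a;
    mat cn = zf % c + zi % zg;
    mat tc = tanh(cn);
    h = zo % tc;
    cc.i[k] = zi; cc.f[k] = zf; cc.g[k] = zg; cc.o[k] = zo;
    cc.c[k] = c; cc.tc[k] = tc; // cc.c stores c_{t-1}
    c = cn;
    cc.h[k] = h;
  }
}

struct DirGrad {
  mat dW, dU;
  rowvec db;
};

// dh_out[k]: gradient flowing into h at scan position k.
// dx[k]: gradient wrt the (unmasked) input consumed at scan position k.
static void lstm_backward(const LstmDir& d, const DirCache& cc,
                          const std::vector<mat>& dh_out,
                          const mat& min, const mat& mrec, bool use_masks,
                          DirGrad& gg, std::vector<mat>& dx) {
  unsigned u = d.U.n_rows;
  size_t T = dh_out.size();
  unsigned B = cc.h[0].n_rows;
  gg.dW.zeros(d.W.n_rows, d.W.n_cols);
  gg.dU.zeros(d.U.n_rows, d.U.n_cols);
  gg.db.zeros(4 * u);
  dx.assign(T, mat());
  mat dh_next(B, u, fill::zeros), dc_next(B, u, fill::zeros);
  for (int k = (int)T - 1; k >= 0; --k) {
    mat dh = dh_out[k] + dh_next;
    mat dzo = dh % cc.tc[k];
    mat dc = dh % cc.o[k] % (1.0 - square(cc.tc[k])) + dc_next;
    mat dzf = dc % cc.c[k];
    mat dzi = dc % cc.g[k];
    mat dzg = dc % cc.i[k];
    dc_next = dc % cc.f[k];
    mat dz(B, 4 * u);
    dz.cols(0, u - 1) = dzi % cc.i[k] % (1.0 - cc.i[k]);
    dz.cols(u, 2 * u - 1) = dzf % cc.f[k] % (1.0 - cc.f[k]);
    dz.cols(2 * u, 3 * u - 1) = dzg % (1.0 - square(cc.g[k]));
    dz.cols(3 * u, 4 * u - 1) = dzo % cc.o[k] % (1.0 - cc.o[k]);
    gg.dW += cc.ain[k].t() * dz;
    mat hin = use_masks ? mat(cc.hprev[k] % mrec) : cc.hprev[k];
    gg.dU += hin.t() * dz;
    gg.db += sum(dz, 0);
    dh_next = dz * d.U.t();
    if (use_masks) dh_next %= mrec;
    mat dxk = dz * d.W.t();
    if (use_masks) dxk %= min;
    dx[k] = dxk;
  }
}

// ---- full-network forward (inference: running BN stats, no dropout) ----
static mat forward_eval(const Net& net, const cube& X, uword from, uword to) {
  uword B = to - from;
  uword T = X.n_cols;
  std::vector<mat> seq(T);
  for (uword t = 0; t < T; ++t) {
    mat xt(B, X.n_slices);
    for (uword ff = 0; ff < X.n_slices; ++ff)
      for (uword i = 0; i < B; ++i) xt(i, ff) = X(from + i, t, ff);
    seq[t] = xt;
  }
  std::vector<int> fsteps(T), bsteps(T);
  for (uword t = 0; t < T; ++t) { fsteps[t] = t; bsteps[t] = T - 1 - t; }
  mat dummy;
  for (size_t l = 0; l < net.layers.size(); ++l) {
    const Layer& L = net.layers[l];
    DirCache cf, cb;
    lstm_scan(L.fwd, seq, fsteps, dummy, dummy, false, cf);
    lstm_scan(L.bwd, seq, bsteps, dummy, dummy, false, cb);
    if (l + 1 == net.layers.size()) {
      seq.assign(1, join_rows(cf.h[T - 1], cb.h[T - 1]));
      break;
    }
    std::vector<mat> out(T);
    for (uword t = 0; t < T; ++t)
      out[t] = join_rows(cf.h[t], cb.h[(T - 1) - t]);
    seq = out;
  }
  mat a1 = seq[0] * net.W1;
  a1.each_row() += net.b1;
  a1 = clamp(a1, 0.0, datum::inf); // ReLU
  mat xhat = a1;
  xhat.each_row() -= net.rmean;
  xhat.each_row() /= sqrt(net.rvar + BN_EPS);
  xhat.each_row() %= net.gamma;
  xhat.each_row() += net.beta;
  mat logits = xhat * net.W2;
  logits.each_row() += net.b2;
  logits.each_col() -= max(logits, 1);
  mat ex = exp(logits);
  ex.each_col() /= sum(ex, 1);
  return ex;
}

// [[Rcpp::export(name = ".bilstm_predict_cpp")]]
arma::mat bilstm_predict_cpp(Rcpp::List weights, arma::cube X, int batch_size) {
  Net net = parse_net(weights);
  uword n = X.n_rows;
  mat probs(n, net.b2.n_elem);
  for (uword at = 0; at < n; at += batch_size) {
    uword to = std::min<uword>(at + batch_size, n);
    probs.rows(at, to - 1) = forward_eval(net, X, at, to);
  }
  return probs;
}

// ---- one training batch: forward with caches, loss, full backward -----
struct BatchMasks {
  std::vector<mat> min_f, min_b, mrec_f, mrec_b;
  mat mdense;
};

struct BatchGrads {
  std::vector<DirGrad> gf, gb;
  mat dW1, dW2;
  rowvec db1, dgamma, dbeta, db2;
  double loss = 0.0;
  uword correct = 0;
};

static void batch_fwd_bwd(Net& net, std::vector<mat> seq, const ivec& yb,
                          const BatchMasks& mk, const vec& class_weights,
                          bool update_bn_stats, BatchGrads& out) {
  size_t nlay = net.layers.size();
  uword T = seq.size();
  uword B = seq[0].n_rows;
  bool weighted = class_weights.n_elem == net.b2.n_elem;
  std::vector<int> fsteps(T), bsteps(T);
  for (uword t = 0; t < T; ++t) { fsteps[t] = t; bsteps[t] = T - 1 - t; }
  std::vector<DirCache> cfs(nlay), cbs(nlay);
  mat head_in;
  for (size_t l = 0; l < nlay; ++l) {
    Layer& L = net.layers[l];
    lstm_scan(L.fwd, seq, fsteps, mk.min_f[l], mk.mrec_f[l], true, cfs[l]);
    lstm_scan(L.bwd, seq, bsteps, mk.min_b[l], mk.mrec_b[l], true, cbs[l]);
    if (l + 1 == nlay) {
      head_in = join_rows(cfs[l].h[T - 1], cbs[l].h[T - 1]);
    } else {
      std::vector<mat> nxt(T);
      for (uword t = 0; t < T; ++t)
        nxt[t] = join_rows(cfs[l].h[t], cbs[l].h[(T - 1) - t]);
      seq = nxt;
    }
  }
  // dense head with batch-statistics normalization
  mat z1 = head_in * net.W1;
  z1.each_row() += net.b1;
  mat a1 = clamp(z1, 0.0, datum::inf);
  rowvec mu = mean(a1, 0);
  mat cent = a1;
  cent.each_row() -= mu;
  rowvec var = mean(square(cent), 0);
  rowvec istd = 1.0 / sqrt(var + BN_EPS);
  mat xhat = cent;
  xhat.each_row() %= istd;
  mat ybn = xhat;
  ybn.each_row() %= net.gamma;
  ybn.each_row() += net.beta;
  if (update_bn_stats) {
    net.rmean = BN_MOMENTUM * net.rmean + (1.0 - BN_MOMENTUM) * mu;
    net.rvar = BN_MOMENTUM * net.rvar + (1.0 - BN_MOMENTUM) * var;
  }
  mat hdo = ybn % mk.mdense;
  mat logits = hdo * net.W2;
  logits.each_row() += net.b2;
  logits.each_col() -= max(logits, 1);
  mat ex = exp(logits);
  mat probs = ex;
  probs.each_col() /= sum(ex, 1);
  mat dlogits = probs;
  double bloss = 0.0;
  for (uword i = 0; i < B; ++i) {
    double w = weighted ? class_weights[yb[i]] : 1.0;
    bloss += -w * std::log(std::max(probs(i, yb[i]), 1e-12));
    dlogits(i, yb[i]) -= 1.0;
    dlogits.row(i) *= w / (double)B;
    if ((int)index_max(probs.row(i)) == yb[i]) ++out.correct;
  }
  out.loss = bloss / B;
  // ---- backward ----
  out.dW2 = hdo.t() * dlogits;
  out.db2 = sum(dlogits, 0);
  mat dhdo = dlogits * net.W2.t();
  mat dybn = dhdo % mk.mdense;
  out.dgamma = sum(dybn % xhat, 0);
  out.dbeta = sum(dybn, 0);
  mat dxhat = dybn;
  dxhat.each_row() %= net.gamma;
  rowvec sum_dxhat = sum(dxhat, 0);
  rowvec sum_dxhat_xhat = sum(dxhat % xhat, 0);
  mat da1 = dxhat;
  da1.each_row() -= sum_dxhat / (double)B;
  mat tmp = xhat;
  tmp.each_row() %= sum_dxhat_xhat / (double)B;
  da1 -= tmp;
  da1.each_row() %= istd;
  mat dz1 = da1 % conv_to<mat>::from(z1 > 0.0);
  out.dW1 = head_in.t() * dz1;
  out.db1 = sum(dz1, 0);
  mat dhead = dz1 * net.W1.t();
  out.gf.resize(nlay);
  out.gb.resize(nlay);
  std::vector<mat> dseq;
  for (int l = (int)nlay - 1; l >= 0; --l) {
    Layer& L = net.layers[l];
    std::vector<mat> dh_f(T, mat(B, L.u, fill::zeros));
    std::vector<mat> dh_b(T, mat(B, L.u, fill::zeros));
    if (l == (int)nlay - 1) {
      dh_f[T - 1] = dhead.cols(0, L.u - 1);
      dh_b[T - 1] = dhead.cols(L.u, 2 * L.u - 1);
    } else {
      // dseq[t] is the gradient wrt [hf_t, hb at scan position T-1-t]
      for (uword t = 0; t < T; ++t) {
        dh_f[t] += dseq[t].cols(0, L.u - 1);
        dh_b[(T - 1) - t] += dseq[t].cols(L.u, 2 * L.u - 1);
      }
    }
    std::vector<mat> dx_f, dx_b;
    lstm_backward(L.fwd, cfs[l], dh_f, mk.min_f[l], mk.mrec_f[l], true,
                  out.gf[l], dx_f);
    lstm_backward(L.bwd, cbs[l], dh_b, mk.min_b[l], mk.mrec_b[l], true,
                  out.gb[l], dx_b);
    if (l > 0) {
      dseq.assign(T, mat());
      for (uword t = 0; t < T; ++t)
        dseq[t] = dx_f[t] + dx_b[(T - 1) - t];
    }
  }
}

static BatchMasks ones_masks(const Net& net, uword B) {
  BatchMasks mk;
  for (const auto& L : net.layers) {
    mk.min_f.push_back(ones<mat>(B, L.fwd.W.n_rows));
    mk.min_b.push_back(ones<mat>(B, L.fwd.W.n_rows));
    mk.mrec_f.push_back(ones<mat>(B, L.u));
    mk.mrec_b.push_back(ones<mat>(B, L.u));
  }
  mk.mdense = ones<mat>(B, net.b1.n_elem);
  return mk;
}

// Loss and analytic gradients on one batch without dropout (used by the
// finite-difference gradient checks in the test suite).
// [[Rcpp::export(name = ".bilstm_lossgrad_cpp")]]
Rcpp::List bilstm_lossgrad_cpp(Rcpp::List weights, arma::cube X, arma::ivec y) {
  Net net = parse_net(weights);
  uword n = X.n_rows, T = X.n_cols, D = X.n_slices;
  std::vector<mat> seq(T, mat(n, D));
  for (uword i = 0; i < n; ++i)
    for (uword t = 0; t < T; ++t)
      for (uword ff = 0; ff < D; ++ff) seq[t](i, ff) = X(i, t, ff);
  BatchMasks mk = ones_masks(net, n);
  BatchGrads gg;
  batch_fwd_bwd(net, seq, y, mk, vec(), false, gg);
  Rcpp::List glayers(net.layers.size());
  for (size_t l = 0; l < net.layers.size(); ++l) {
    glayers[l] = Rcpp::List::create(
      Rcpp::Named("Wf") = gg.gf[l].dW, Rcpp::Named("Uf") = gg.gf[l].dU,
      Rcpp::Named("bf") = gg.gf[l].db, Rcpp::Named("Wb") = gg.gb[l].dW,
      Rcpp::Named("Ub") = gg.gb[l].dU, Rcpp::Named("bb") = gg.gb[l].db);
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = gg.loss,
    Rcpp::Named("layers") = glayers,
    Rcpp::Named("W1") = gg.dW1, Rcpp::Named("b1") = gg.db1,
    Rcpp::Named("gamma") = gg.dgamma, Rcpp::Named("beta") = gg.dbeta,
    Rcpp::Named("W2") = gg.dW2, Rcpp::Named("b2") = gg.db2);
}

// Collect pointers to trainable parameters in a fixed order.
static std::vector<mat*> trainable(Net& net, std::vector<rowvec*>& rows) {
  std::vector<mat*> ps;
  rows.clear();
  for (auto& L : net.layers) {
    ps.push_back(&L.fwd.W); ps.push_back(&L.fwd.U);
    ps.push_back(&L.bwd.W); ps.push_back(&L.bwd.U);
    rows.push_back(&L.fwd.b); rows.push_back(&L.bwd.b);
  }
  ps.push_back(&net.W1); ps.push_back(&net.W2);
  rows.push_back(&net.b1); rows.push_back(&net.gamma);
  rows.push_back(&net.beta); rows.push_back(&net.b2);
  return ps;
}

struct Adam {
  std::vector<mat> m, v;
  std::vector<rowvec> mr, vr;
  long t = 0;
  void init(const std::vector<mat*>& ps, const std::vector<rowvec*>& rs) {
    for (auto* p : ps) { m.push_back(zeros<mat>(size(*p)));
                         v.push_back(zeros<mat>(size(*p))); }
    for (auto* r : rs) { mr.push_back(zeros<rowvec>(r->n_elem));
                         vr.push_back(zeros<rowvec>(r->n_elem)); }
  }
  void step(std::vector<mat*>& ps, const std::vector<mat>& gs,
            std::vector<rowvec*>& rs, const std::vector<rowvec>& gr,
            double lr) {
    ++t;
    double b1c = 1.0 - std::pow(0.9, (double)t);
    double b2c = 1.0 - std::pow(0.999, (double)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = 0.9 * m[i] + 0.1 * gs[i];
      v[i] = 0.999 * v[i] + 0.001 * square(gs[i]);
      *ps[i] -= lr * (m[i] / b1c) / (sqrt(v[i] / b2c) + ADAM_EPS);
    }
    for (size_t i = 0; i < rs.size(); ++i) {
      mr[i] = 0.9 * mr[i] + 0.1 * gr[i];
      vr[i] = 0.999 * vr[i] + 0.001 * square(gr[i]);
      *rs[i] -= lr * (mr[i] / b1c) / (sqrt(vr[i] / b2c) + ADAM_EPS);
    }
  }
};

// [[Rcpp::export(name = ".bilstm_train_cpp")]]
Rcpp::List bilstm_train_cpp(Rcpp::List weights, arma::cube X,
                            arma::ivec y, int epochs, int batch_size,
                            arma::vec lr_per_epoch, double dropout,
                            double recurrent_dropout, double dense_dropout,
                            arma::vec class_weights, int seed,
                            Rcpp::Nullable<Rcpp::NumericVector> Xval_ = R_NilValue,
                            Rcpp::Nullable<Rcpp::IntegerVector> yval_ = R_NilValue) {
  Net net = parse_net(weights);
  uword n = X.n_rows, T = X.n_cols, D = X.n_slices;
  size_t nlay = net.layers.size();
  bool has_val = Xval_.isNotNull();
  cube Xval;
  ivec yval;
  if (has_val) {
    Rcpp::NumericVector xv(Xval_);
    Rcpp::IntegerVector dims = xv.attr("dim");
    Xval = cube(xv.begin(), dims[0], dims[1], dims[2]);
    yval = Rcpp::as<ivec>(yval_);
  }
  std::vector<rowvec*> rs;
  std::vector<mat*> ps = trainable(net, rs);
  Adam adam;
  adam.init(ps, rs);
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;
  std::vector<double> hist_loss, hist_acc, hist_val;

  auto make_mask = [&](uword B, uword d, double p) {
    mat mask(B, d);
    if (p <= 0.0) { mask.ones(); return mask; }
    double keep = 1.0 - p;
    for (uword i = 0; i < B; ++i)
      for (uword j = 0; j < d; ++j)
        mask(i, j) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    return mask;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double lr = lr_per_epoch[std::min<uword>(ep, lr_per_epoch.n_elem - 1)];
    double ep_loss = 0.0;
    uword ep_correct = 0, n_batches = 0;
    for (uword at = 0; at < n; at += batch_size) {
      uword B = std::min<uword>(batch_size, n - at);
      std::vector<mat> seq(T, mat(B, D));
      ivec yb(B);
      for (uword i = 0; i < B; ++i) {
        uword src = order[at + i];
        yb[i] = y[src];
        for (uword t = 0; t < T; ++t)
          for (uword ff = 0; ff < D; ++ff) seq[t](i, ff) = X(src, t, ff);
      }
      BatchMasks mk;
      for (size_t l = 0; l < nlay; ++l) {
        uword d = net.layers[l].fwd.W.n_rows;
        mk.min_f.push_back(make_mask(B, d, dropout));
        mk.min_b.push_back(make_mask(B, d, dropout));
        mk.mrec_f.push_back(make_mask(B, net.layers[l].u, recurrent_dropout));
        mk.mrec_b.push_back(make_mask(B, net.layers[l].u, recurrent_dropout));
      }
      mk.mdense = make_mask(B, net.b1.n_elem, dense_dropout);
      BatchGrads gg;
      batch_fwd_bwd(net, seq, yb, mk, class_weights, true, gg);
      ep_loss += gg.loss;
      ep_correct += gg.correct;
      ++n_batches;
      std::vector<mat> gmats;
      std::vector<rowvec> grows;
      for (size_t l = 0; l < nlay; ++l) {
        gmats.push_back(gg.gf[l].dW); gmats.push_back(gg.gf[l].dU);
        gmats.push_back(gg.gb[l].dW); gmats.push_back(gg.gb[l].dU);
        grows.push_back(gg.gf[l].db); grows.push_back(gg.gb[l].db);
      }
      gmats.push_back(gg.dW1); gmats.push_back(gg.dW2);
      grows.push_back(gg.db1); grows.push_back(gg.dgamma);
      grows.push_back(gg.dbeta); grows.push_back(gg.db2);
      adam.step(ps, gmats, rs, grows, lr);
    }
    hist_loss.push_back(ep_loss / n_batches);
    hist_acc.push_back((double)ep_correct / n);
    if (has_val) {
      uword correct = 0;
      for (uword at = 0; at < Xval.n_rows; at += batch_size) {
        uword to = std::min<uword>(at + batch_size, Xval.n_rows);
        mat p = forward_eval(net, Xval, at, to);
        for (uword i = 0; i < p.n_rows; ++i)
          if ((int)index_max(p.row(i)) == yval[at + i]) ++correct;
      }
      hist_val.push_back((double)correct / Xval.n_rows);
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(net),
    Rcpp::Named("loss") = hist_loss,
    Rcpp::Named("accuracy") = hist_acc,
    Rcpp::Named("val_accuracy") = hist_val);
}
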