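// Recurrent fusion core: stacked LSTM blocks with inter-block dropout and a
// time-distributed affine head, trained by backpropagation through time with
// Adam, reduce-on-plateau learning-rate scheduling and early stopping.
// All stochastic elements (dropout masks, epoch shuffles) come from one
// Mersenne-Twister generator seeded from R, so training is bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

constexpr double EPS = 1e-12;

struct LayerParam {
  mat W;    // D x 4H   input weights, gate order (i, f, g, o)
  mat U;    // H x 4H   recurrent weights
  rowvec b; // 4H
};

struct Net {
  std::vector<LayerParam> layers;
  vec dw;    // dense head weights (H_last)
  double db; // dense head bias
};

Net net_from_list(const List& wl) {
  Net net;
  List ll = wl["layers"];
  for (int i = 0; i < ll.size(); ++i) {
    List li = ll[i];
    LayerParam p;
    p.W = Rcpp::as<mat>(li["W"]);
    p.U = Rcpp::as<mat>(li["U"]);
    p.b = Rcpp::as<rowvec>(li["b"]);
    net.layers.push_back(std::move(p));
  }
  List dl = wl["dense"];
  net.dw = Rcpp::as<vec>(dl["w"]);
  net.db = Rcpp::as<double>(dl["b"]);
  return net;
}

List net_to_list(const Net& net) {
  List ll(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    ll[i] = List::create(Named("W") = net.layers[i].W,
                         Named("U") = net.layers[i].U,
                         Named("b") = net.layers[i].b);
  }
  return List::create(Named("layers") = ll,
                      Named("dense") = List::create(Named("w") = net.dw,
                                                    Named("b") = net.db));
}

Net zeros_like(const Net& net) {
  Net z;
  for (const auto& p : net.layers) {
    LayerParam q;
    q.W.zeros(p.W.n_rows, p.W.n_cols);
    q.U.zeros(p.U.n_rows, p.U.n_cols);
    q.b.zeros(p.b.n_elem);
    z.layers.push_back(std::move(q));
  }
  z.dw.zeros(net.dw.n_elem);
  z.db = 0.0;
  return z;
}

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  void shuffle(std::vector<uword>& v) {
    for (size_t i = v.size(); i > 1; --i) {
      size_t j = static_cast<size_t>(unif() * i);
      if (j >= i) j = i - 1;
      std::swap(v[i - 1], v[j]);
    }
  }
};

struct LayerCache {
  cube Xin;                  // B x D x T input to the block (post-dropout of the block below)
  cube I, F, G, O, C, Th, H; // gate activations, cell state, tanh(cell), output
  cube M;                    // inverted-dropout mask on the block output
  bool has_mask = false;
};

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// X: B x D x T (slice = timestep). Returns predictions B x T.
mat forward(const Net& net, const cube& X, bool training, double dropout,
            Rng* rng, std::vector<LayerCache>* caches) {
  const uword B = X.n_rows, T = X.n_slices;
  cube cur = X;
  const size_t L = net.layers.size();
  if (caches) caches->assign(L, LayerCache());
  for (size_t l = 0; l < L; ++l) {
    const LayerParam& p = net.layers[l];
    const uword H = p.U.n_rows;
    mat h(B, H, fill::zeros), c(B, H, fill::zeros);
    const bool keep = caches != nullptr;
    LayerCache* cc = keep ? &(*caches)[l] : nullptr;
    if (keep) {
      cc->Xin = cur;
      cc->I.set_size(B, H, T); cc->F.set_size(B, H, T); cc->G.set_size(B, H, T);
      cc->O.set_size(B, H, T); cc->C.set_size(B, H, T); cc->Th.set_size(B, H, T);
    }
    cube Hout(B, H, T);
    for (uword t = 0; t < T; ++t) {
      mat A = cur.slice(t) * p.W + h * p.U;
      A.each_row() += p.b;
      mat gi = sigm(A.cols(0, H - 1));
      mat gf = sigm(A.cols(H, 2 * H - 1));
      mat gg = tanh(A.cols(2 * H, 3 * H - 1));
      mat go = sigm(A.cols(3 * H, 4 * H - 1));
      c = gf % c + gi % gg;
      mat th = tanh(c);
      h = go % th;
      Hout.slice(t) = h;
      if (keep) {
        cc->I.slice(t) = gi; cc->F.slice(t) = gf; cc->G.slice(t) = gg;
        cc->O.slice(t) = go; cc->C.slice(t) = c;  cc->Th.slice(t) = th;
      }
    }
    if (keep) cc->H = Hout;
    if (training && dropout > 0.0) {
      cube M(B, H, T);
      const double kp = 1.0 - dropout;
      for (uword i = 0; i < M.n_elem; ++i)
        M(i) = (rng->unif() < kp) ? 1.0 / kp : 0.0;
      Hout %= M;
      if (keep) { cc->M = M; cc->has_mask = true; }
    }
    cur = Hout;
  }
  mat P(B, T);
  for (uword t = 0; t < T; ++t)
    P.col(t) = cur.slice(t) * net.dw + net.db;
  return P;
}

// Combined loss: w_rmse * RMSE + w_r * (1 - Pearson r), averaged over the
// batch. A constant (degenerate) prediction or target scores the r term as
// its maximal penalty 1 with zero gradient.
double loss_grad(const mat& P, const mat& Yb, double w_rmse, double w_r, mat* dP) {
  const uword B = P.n_rows, T = P.n_cols;
  double total = 0.0;
  if (dP) dP->zeros(B, T);
  for (uword b = 0; b < B; ++b) {
    rowvec p = P.row(b), y = Yb.row(b);
    rowvec e = p - y;
    double mse = accu(e % e) / T;
    double rm = std::sqrt(mse);
    double lb = w_rmse * rm;
    rowvec gr(T, fill::zeros);
    if (w_rmse > 0.0 && rm > EPS) gr += (w_rmse / (T * rm)) * e;
    rowvec pc = p - mean(p), yc = y - mean(y);
    double sxx = accu(pc % pc), syy = accu(yc % yc);
    if (sxx < EPS || syy < EPS) {
      lb += w_r;
    } else {
      double denom = std::sqrt(sxx * syy);
      double r = accu(pc % yc) / denom;
      lb += w_r * (1.0 - r);
      rowvec dr = yc / denom - (r / sxx) * pc;
      gr -= w_r * dr;
    }
    total += lb;
    if (dP) dP->row(b) = gr / B;
  }
  return total / B;
}

void backward(const Net& net, std::vector<LayerCache>& cs, const mat& dP, Net& g) {
  const size_t L = net.layers.size();
  const uword B = dP.n_rows, T = dP.n_cols;
  cube top = cs[L - 1].H;
  if (cs[L - 1].has_mask) top %= cs[L - 1].M;
  const uword HL = top.n_cols;
  g.dw.zeros(HL);
  g.db = 0.0;
  cube dHdrop(B, HL, T);
  for (uword t = 0; t < T; ++t) {
    g.dw += top.slice(t).t() * dP.col(t);
    g.db += accu(dP.col(t));
    dHdrop.slice(t) = dP.col(t) * net.dw.t();
  }
  for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
    LayerCache& cc = cs[l];
    const LayerParam& p = net.layers[l];
    const uword H = p.U.n_rows, D = p.W.n_rows;
    cube dHl = dHdrop;
    if (cc.has_mask) dHl %= cc.M;
    mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
    g.layers[l].W.zeros(D, 4 * H);
    g.layers[l].U.zeros(H, 4 * H);
    g.layers[l].b.zeros(4 * H);
    cube dX(B, D, T);
    const mat zsBH(B, H, fill::zeros);
    for (int t = static_cast<int>(T) - 1; t >= 0; --t) {
      mat dh = dHl.slice(t) + dh_next;
      const mat& gi = cc.I.slice(t);
      const mat& gf = cc.F.slice(t);
      const mat& gg = cc.G.slice(t);
      const mat& go = cc.O.slice(t);
      const mat& th = cc.Th.slice(t);
      const mat& cprev = (t > 0) ? cc.C.slice(t - 1) : zsBH;
      mat dgo = dh % th;
      mat dao = dgo % go % (1.0 - go);
      mat dc = dh % go % (1.0 - th % th) + dc_next;
      mat dai = (dc % gg) % gi % (1.0 - gi);
      mat dag = (dc % gi) % (1.0 - gg % gg);
      mat daf = (dc % cprev) % gf % (1.0 - gf);
      dc_next = dc % gf;
      mat dA = join_rows(dai, daf, dag, dao);
      g.layers[l].W += cc.Xin.slice(t).t() * dA;
      const mat& hprev = (t > 0) ? cc.H.slice(t - 1) : zsBH;
      g.layers[l].U += hprev.t() * dA;
      g.layers[l].b += sum(dA, 0);
      dh_next = dA * p.U.t();
      dX.slice(t) = dA * p.W.t();
    }
    dHdrop = dX;
  }
}

double grad_sq_norm(const Net& g) {
  double s = accu(g.dw % g.dw) + g.db * g.db;
  for (const auto& p : g.layers)
    s += accu(p.W % p.W) + accu(p.U % p.U) + accu(p.b % p.b);
  return s;
}

void grad_scale(Net& g, double s) {
  g.dw *= s;
  g.db *= s;
  for (auto& p : g.layers) { p.W *= s; p.U *= s; p.b *= s; }
}

struct Adam {
  Net m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Net& w) : m(zeros_like(w)), v(zeros_like(w)) {}
};

inline void adam_mat(mat& w, const mat& g, mat& m, mat& v, const Adam& st, double lr) {
  m = st.b1 * m + (1.0 - st.b1) * g;
  v = st.b2 * v + (1.0 - st.b2) * (g % g);
  double c1 = 1.0 - std::pow(st.b1, static_cast<double>(st.t));
  double c2 = 1.0 - std::pow(st.b2, static_cast<double>(st.t));
  w -= lr * (m / c1) / (sqrt(v / c2) + st.eps);
}

void adam_step(Net& w, const Net& g, Adam& st, double lr) {
  st.t += 1;
  for (size_t l = 0; l < w.layers.size(); ++l) {
    adam_mat(w.layers[l].W, g.layers[l].W, st.m.layers[l].W, st.v.layers[l].W, st, lr);
    adam_mat(w.layers[l].U, g.layers[l].U, st.m.layers[l].U, st.v.layers[l].U, st, lr);
    mat bw(w.layers[l].b), bg(g.layers[l].b), bm(st.m.layers[l].b), bv(st.v.layers[l].b);
    adam_mat(bw, bg, bm, bv, st, lr);
    w.layers[l].b = bw;
    st.m.layers[l].b = bm;
    st.v.layers[l].b = bv;
  }
  mat dw(w.dw), dg(g.dw), dm(st.m.dw), dv(st.v.dw);
  adam_mat(dw, dg, dm, dv, st, lr);
  w.dw = dw; st.m.dw = dm; st.v.dw = dv;
  st.m.db = st.b1 * st.m.db + (1.0 - st.b1) * g.db;
  st.v.db = st.b2 * st.v.db + (1.0 - st.b2) * g.db * g.db;
  double c1 = 1.0 - std::pow(st.b1, static_cast<double>(st.t));
  double c2 = 1.0 - std::pow(st.b2, static_cast<double>(st.t));
  w.db -= lr * (st.m.db / c1) / (std::sqrt(st.v.db / c2) + st.eps);
}

void fill_batch(const cube& X, const mat& Y, const std::vector<uword>& idx,
                cube& Xb, mat& Yb) {
  const uword B = idx.size(), T = X.n_rows, D = X.n_cols;
  Xb.set_size(B, D, T);
  Yb.set_size(B, T);
  for (uword b = 0; b < B; ++b) {
    const mat& s = X.slice(idx[b]); // T x D
    for (uword t = 0; t < T; ++t) Xb.slice(t).row(b) = s.row(t);
    Yb.row(b) = Y.col(idx[b]).t();
  }
}

double eval_loss(const Net& net, const cube& X, const mat& Y,
                 const std::vector<uword>& idx, double w_rmse, double w_r,
                 uword batch_size) {
  double tot = 0.0;
  uword n = idx.size();
  for (uword s = 0; s < n; s += batch_size) {
    uword e = std::min(n, s + batch_size);
    std::vector<uword> chunk(idx.begin() + s, idx.begin() + e);
    cube Xb; mat Yb;
    fill_batch(X, Y, chunk, Xb, Yb);
    mat P = forward(net, Xb, false, 0.0, nullptr, nullptr);
    tot += loss_grad(P, Yb, w_rmse, w_r, nullptr) * chunk.size();
  }
  return tot / n;
}

} // namespace

// [[Rcpp::export]]
List lstm_train_cpp(List w0, arma::cube X, arma::mat Y,
                    arma::uvec train_idx, arma::uvec val_idx,
                    List hp, int seed) {
  Net net = net_from_list(w0);
  const int epochs = Rcpp::as<int>(hp["epochs"]);
  const uword batch_size = Rcpp::as<int>(hp["batch_size"]);
  double lr = Rcpp::as<double>(hp["lr"]);
  const double lr_factor = Rcpp::as<double>(hp["lr_factor"]);
  const int lr_patience = Rcpp::as<int>(hp["lr_patience"]);
  const double lr_floor = Rcpp::as<double>(hp["lr_floor"]);
  const int early_patience = Rcpp::as<int>(hp["early_stop_patience"]);
  const double w_rmse = Rcpp::as<double>(hp["w_rmse"]);
  const double w_r = Rcpp::as<double>(hp["w_r"]);
  const double dropout = Rcpp::as<double>(hp["dropout"]);
  const double clip_norm = Rcpp::as<double>(hp["clip_norm"]);

  std::vector<uword> tr(train_idx.n_elem), va(val_idx.n_elem);
  for (uword i = 0; i < train_idx.n_elem; ++i) tr[i] = train_idx[i] - 1;
  for (uword i = 0; i < val_idx.n_elem; ++i) va[i] = val_idx[i] - 1;

  Rng rng(static_cast<uint64_t>(seed));
  Adam opt(net);
  Net best = net;
  double best_monitor = datum::inf;
  int lr_wait = 0, stop_wait = 0, best_epoch = 0, stopped = epochs;
  std::vector<double> log_train, log_val, log_lr;

  for (int ep = 1; ep <= epochs; ++ep) {
    rng.shuffle(tr);
    double ep_loss = 0.0;
    uword seen = 0;
    for (uword s = 0; s < tr.size(); s += batch_size) {
      uword e = std::min<uword>(tr.size(), s + batch_size);
      std::vector<uword> bidx(tr.begin() + s, tr.begin() + e);
      cube Xb; mat Yb;
      fill_batch(X, Y, bidx, Xb, Yb);
      std::vector<LayerCache> caches;
      mat P = forward(net, Xb, true, dropout, &rng, &caches);
      mat dP;
      double lb = loss_grad(P, Yb, w_rmse, w_r, &dP);
      if (!std::isfinite(lb))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep);
      Net g = zeros_like(net);
      backward(net, caches, dP, g);
      double nrm = std::sqrt(grad_sq_norm(g));
      if (clip_norm > 0.0 && nrm > clip_norm) grad_scale(g, clip_norm / nrm);
      adam_step(net, g, opt, lr);
      ep_loss += lb * bidx.size();
      seen += bidx.size();
    }
    ep_loss /= seen;
    double val_loss = va.empty()
      ? ep_loss
      : eval_loss(net, X, Y, va, w_rmse, w_r, batch_size);
    log_train.push_back(ep_loss);
    log_val.push_back(val_loss);
    log_lr.push_back(lr);

    if (val_loss < best_monitor - 1e-9) {
      best_monitor = val_loss;
      best = net;
      best_epoch = ep;
      lr_wait = 0;
      stop_wait = 0;
    } else {
      ++lr_wait;
      ++stop_wait;
      if (lr_wait >= lr_patience) {
        lr = std::max(lr * lr_factor, lr_floor);
        lr_wait = 0;
      }
      if (stop_wait >= early_patience) { stopped = ep; break; }
    }
    stopped = ep;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    Named("weights") = net_to_list(best),
    Named("final_weights") = net_to_list(net),
    Named("train_loss") = log_train,
    Named("val_loss") = log_val,
    Named("lr") = log_lr,
    Named("best_epoch") = best_epoch,
    Named("stopped_epoch") = stopped);
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(List w, arma::cube X) {
  Net net = net_from_list(w);
  const uword N = X.n_slices, T = X.n_rows;
  mat out(T, N);
  const uword chunk = 64;
  std::vector<uword> idx;
  mat Ydummy(T, N, fill::zeros);
  for (uword s = 0; s < N; s += chunk) {
    uword e = std::min(N, s + chunk);
    idx.clear();
    for (uword i = s; i < e; ++i) idx.push_back(i);
    cube Xb; mat Yb;
    fill_batch(X, Ydummy, idx, Xb, Yb);
    mat P = forward(net, Xb, false, 0.0, nullptr, nullptr);
    for (uword i = s; i < e; ++i) out.col(i) = P.row(i - s).t();
  }
  return out;
}

// Classic dynamic-programming DTW: local cost is the squared difference,
// the returned distance is the square root of the optimal path's summed
// squared differences (no warping-window constraint).
// [[Rcpp::export]]
double dtw_distance_cpp(arma::vec x, arma::vec y) {
  const uword n = x.n_elem, m = y.n_elem;
  vec prev(m + 1, fill::value(datum::inf));
  vec curr(m + 1);
  prev[0] = 0.0;
  for (uword i = 1; i <= n; ++i) {
    curr.fill(datum::inf);
    for (uword j = 1; j <= m; ++j) {
      double d = x[i - 1] - y[j - 1];
      double best = std::min(prev[j], std::min(curr[j - 1], prev[j - 1]));
      curr[j] = d * d + best;
    }
    prev = curr;
  }
  return std::sqrt(prev[m]);
}
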