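// Small per-participant sequence classifiers: 1-D CNN, LSTM and a hybrid
// CNN-LSTM, trained by backpropagation with Adam on binary cross-entropy.
// Windows are tiny (<= 10 time steps, 4 features), so everything is written
// per-sample with dense linear algebra; batching only accumulates gradients.
//
// Weight layouts (lists of matrices, created and seeded on the R side):
//   cnn:      W1 (k1*f x F), b1 (F x 1), W2 (k2*F x F), b2 (F x 1),
//             W3 (flat x D), b3 (D x 1), W4 (D x 1), b4 (1 x 1)
//   lstm:     Wf, Wi, Wo, Wc ((H+f) x H), bf, bi, bo, bc (H x 1),
//             Wd (H x D), bd (D x 1), Wv (D x 1), bv (1 x 1)
//   cnn_lstm: W1 (k*f x F), b1 (F x 1), Wf..Wc ((H+d) x H) with d the
//             flattened conv output of one subsequence, bf..bc (H x 1),
//             Wv (H x 1), bv (1 x 1)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int FAMILY_CNN = 1;
static const int FAMILY_LSTM = 2;
static const int FAMILY_CNN_LSTM = 3;

static inline double sigmoid1(double z) { return 1.0 / (1.0 + std::exp(-z)); }
static inline vec sigmoid(const vec& z) { return 1.0 / (1.0 + exp(-z)); }
static inline mat relu(const mat& z) {
  mat r = z;
  r.elem(find(z < 0)).zeros();
  return r;
}
static inline mat relu_grad(const mat& z) { return conv_to<mat>::from(z > 0); }

// ---- 1-D convolution via im2col ------------------------------------------

static mat im2col(const mat& X, int k) {
  const int L = (int)X.n_rows - k + 1;
  const int C = (int)X.n_cols;
  mat A(L, k * C);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < C; ++c)
        A(i, j * C + c) = X(i + j, c);
  return A;
}

static void im2col_back(mat& dX, const mat& dA, int k) {
  const int L = (int)dA.n_rows;
  const int C = (int)dX.n_cols;
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < C; ++c)
        dX(i + j, c) += dA(i, j * C + c);
}

// Max pooling over time with stride = pool size.  When the input is already
// shorter than one pool, the stage degrades to the identity (empty index
// matrix marks the no-op).  Ties resolve to the earliest time step.
static mat maxpool(const mat& H, int p, umat& idx) {
  const int L = (int)H.n_rows, C = (int)H.n_cols;
  const int Lp = L / p;
  if (Lp == 0) { idx.set_size(0, 0); return H; }
  mat P(Lp, C);
  idx.set_size(Lp, C);
  for (int b = 0; b < Lp; ++b)
    for (int c = 0; c < C; ++c) {
      int best = b * p;
      double bv = H(best, c);
      for (int j = 1; j < p; ++j)
        if (H(b * p + j, c) > bv) { bv = H(b * p + j, c); best = b * p + j; }
      P(b, c) = bv;
      idx(b, c) = best;
    }
  return P;
}

static mat maxpool_back(const mat& dP, const umat& idx, int L) {
  if (idx.n_elem == 0) return dP;
  mat dH(L, dP.n_cols, fill::zeros);
  for (uword b = 0; b < dP.n_rows; ++b)
    for (uword c = 0; c < dP.n_cols; ++c)
      dH(idx(b, c), c) += dP(b, c);
  return dH;
}

// ---- CNN ------------------------------------------------------------------

struct CnnCache {
  mat A1, Z1, P1, A2, Z2, P2;
  umat idx1, idx2;
  int L1, L2;
  vec f, z3, h3;
  double p;
};

static double cnn_forward(const mat& X, const std::vector<mat>& w,
                          int k1, int k2, int pool, CnnCache* cache) {
  CnnCache local;
  CnnCache& c = cache ? *cache : local;
  c.A1 = im2col(X, k1);
  c.Z1 = c.A1 * w[0];
  c.Z1.each_row() += w[1].t();
  mat H1 = relu(c.Z1);
  c.L1 = (int)H1.n_rows;
  c.P1 = maxpool(H1, pool, c.idx1);
  c.A2 = im2col(c.P1, k2);
  c.Z2 = c.A2 * w[2];
  c.Z2.each_row() += w[3].t();
  mat H2 = relu(c.Z2);
  c.L2 = (int)H2.n_rows;
  c.P2 = maxpool(H2, pool, c.idx2);
  c.f = vectorise(c.P2);
  c.z3 = w[4].t() * c.f + w[5];
  c.h3 = relu(c.z3);
  double z4 = dot(w[6], c.h3) + w[7](0, 0);
  c.p = sigmoid1(z4);
  return c.p;
}

static void cnn_backward(const mat& X, const std::vector<mat>& w,
                         const CnnCache& c, double y, int k1, int k2,
                         std::vector<mat>& g) {
  double dz4 = c.p - y;
  g[6] += dz4 * c.h3;
  g[7](0, 0) += dz4;
  vec dh3 = dz4 * w[6];
  vec dz3 = dh3 % vectorise(relu_grad(c.z3));
  g[4] += c.f * dz3.t();
  g[5] += dz3;
  vec df = w[4] * dz3;
  mat dP2 = reshape(df, c.P2.n_rows, c.P2.n_cols);
  mat dH2 = maxpool_back(dP2, c.idx2, c.L2);
  mat dZ2 = dH2 % relu_grad(c.Z2);
  g[2] += c.A2.t() * dZ2;
  g[3] += sum(dZ2, 0).t();
  mat dA2 = dZ2 * w[2].t();
  mat dP1(c.P1.n_rows, c.P1.n_cols, fill::zeros);
  im2col_back(dP1, dA2, k2);
  mat dH1 = maxpool_back(dP1, c.idx1, c.L1);
  mat dZ1 = dH1 % relu_grad(c.Z1);
  g[0] += c.A1.t() * dZ1;
  g[1] += sum(dZ1, 0).t();
}

// ---- LSTM core (shared by lstm and cnn_lstm) ------------------------------

// One LSTM pass over a sequence of input vectors; caches per-step activations.
struct LstmCache {
  std::vector<vec> z, f, i, o, g, c, c_prev;
  vec h_last;
};

static vec lstm_forward(const std::vector<vec>& xs, const std::vector<mat>& w,
                        int off, int H, LstmCache* cache) {
  vec h(H, fill::zeros), c(H, fill::zeros);
  const size_t T = xs.size();
  if (cache) {
    cache->z.resize(T); cache->f.resize(T); cache->i.resize(T);
    cache->o.resize(T); cache->g.resize(T); cache->c.resize(T);
    cache->c_prev.resize(T);
  }
  for (size_t t = 0; t < T; ++t) {
    vec z = join_cols(h, xs[t]);
    vec ft = sigmoid(w[off + 0].t() * z + w[off + 4]);
    vec it = sigmoid(w[off + 1].t() * z + w[off + 5]);
    vec ot = sigmoid(w[off + 2].t() * z + w[off + 6]);
    vec gt = tanh(w[off + 3].t() * z + w[off + 7]);
    vec c_new = ft % c + it % gt;
    vec h_new = ot % tanh(c_new);
    if (cache) {
      cache->z[t] = z; cache->f[t] = ft; cache->i[t] = it;
      cache->o[t] = ot; cache->g[t] = gt; cache->c[t] = c_new;
      cache->c_prev[t] = c;
    }
    c = c_new;
    h = h_new;
  }
  if (cache) cache->h_last = h;
  return h;
}

// Backpropagation through time; dh_last is the gradient flowing into the
// final hidden state.  Per-step input gradients (the slice of dz below the
// hidden part) are written to dxs when requested (cnn_lstm needs them).
static void lstm_backward(const std::vector<mat>& w, const LstmCache& cache,
                          int off, int H, const vec& dh_last,
                          std::vector<mat>& grad, std::vector<vec>* dxs) {
  const int T = (int)cache.z.size();
  vec dh = dh_last;
  vec dc(H, fill::zeros);
  if (dxs) dxs->resize(T);
  for (int t = T - 1; t >= 0; --t) {
    const vec& ft = cache.f[t];
    const vec& it = cache.i[t];
    const vec& ot = cache.o[t];
    const vec& gt = cache.g[t];
    vec tc = tanh(cache.c[t]);
    vec do_ = dh % tc % ot % (1 - ot);
    dc += dh % ot % (1 - tc % tc);
    vec df = dc % cache.c_prev[t] % ft % (1 - ft);
    vec di = dc % gt % it % (1 - it);
    vec dg = dc % it % (1 - gt % gt);
    grad[off + 0] += cache.z[t] * df.t();
    grad[off + 1] += cache.z[t] * di.t();
    grad[off + 2] += cache.z[t] * do_.t();
    grad[off + 3] += cache.z[t] * dg.t();
    grad[off + 4] += df;
    grad[off + 5] += di;
    grad[off + 6] += do_;
    grad[off + 7] += dg;
    vec dz = w[off + 0] * df + w[off + 1] * di +
             w[off + 2] * do_ + w[off + 3] * dg;
    dh = dz.head(H);
    if (dxs) (*dxs)[t] = dz.tail(dz.n_elem - H);
    dc = dc % ft;
  }
}

// ---- LSTM classifier head -------------------------------------------------

struct LstmHeadCache {
  LstmCache rec;
  vec z3, h3;
  double p;
};

static double lstm_model_forward(const mat& X, const std::vector<mat>& w,
                                 int H, LstmHeadCache* cache) {
  std::vector<vec> xs(X.n_rows);
  for (uword t = 0; t < X.n_rows; ++t) xs[t] = X.row(t).t();
  LstmHeadCache local;
  LstmHeadCache& c = cache ? *cache : local;
  vec h = lstm_forward(xs, w, 0, H, &c.rec);
  c.z3 = w[8].t() * h + w[9];
  c.h3 = relu(c.z3);
  double z4 = dot(w[10], c.h3) + w[11](0, 0);
  c.p = sigmoid1(z4);
  return c.p;
}

static void lstm_model_backward(const std::vector<mat>& w,
                                const LstmHeadCache& c, double y, int H,
                                std::vector<mat>& g) {
  double dz4 = c.p - y;
  g[10] += dz4 * c.h3;
  g[11](0, 0) += dz4;
  vec dh3 = dz4 * w[10];
  vec dz3 = dh3 % vectorise(relu_grad(c.z3));
  g[8] += c.rec.h_last * dz3.t();
  g[9] += dz3;
  vec dh = w[8] * dz3;
  lstm_backward(w, c.rec, 0, H, dh, g, nullptr);
}

// ---- CNN-LSTM hybrid ------------------------------------------------------

// Cut a window into n_sub contiguous subsequences of sub_len rows; the last
// subsequence is padded by repeating the final row when the window length is
// not divisible.
static std::vector<mat> make_subsequences(const mat& X, int n_sub, int sub_len) {
  std::vector<mat> subs(n_sub);
  const int w = (int)X.n_rows;
  for (int s = 0; s < n_sub; ++s) {
    mat sub(sub_len, X.n_cols);
    for (int r = 0; r < sub_len; ++r) {
      int src = std::min(s * sub_len + r, w - 1);
      sub.row(r) = X.row(src);
    }
    subs[s] = sub;
  }
  return subs;
}

struct HybridCache {
  std::vector<mat> A, Z, P;
  std::vector<umat> idx;
  std::vector<int> L;
  LstmCache rec;
  double p;
};

static double hybrid_forward(const mat& X, const std::vector<mat>& w,
                             int n_sub, int sub_len, int k, int pool, int H,
                             HybridCache* cache) {
  HybridCache local;
  HybridCache& c = cache ? *cache : local;
  std::vector<mat> subs = make_subsequences(X, n_sub, sub_len);
  c.A.resize(n_sub); c.Z.resize(n_sub); c.P.resize(n_sub);
  c.idx.resize(n_sub); c.L.resize(n_sub);
  std::vector<vec> xs(n_sub);
  for (int s = 0; s < n_sub; ++s) {
    c.A[s] = im2col(subs[s], k);
    c.Z[s] = c.A[s] * w[0];
    c.Z[s].each_row() += w[1].t();
    mat Hs = relu(c.Z[s]);
    c.L[s] = (int)Hs.n_rows;
    c.P[s] = maxpool(Hs, pool, c.idx[s]);
    xs[s] = vectorise(c.P[s]);
  }
  vec h = lstm_forward(xs, w, 2, H, &c.rec);
  double z4 = dot(w[10], h) + w[11](0, 0);
  c.p = sigmoid1(z4);
  return c.p;
}

static void hybrid_backward(const std::vector<mat>& w, const HybridCache& c,
                            double y, int k, int H, std::vector<mat>& g) {
  double dz4 = c.p - y;
  g[10] += dz4 * c.rec.h_last;
  g[11](0, 0) += dz4;
  vec dh = dz4 * w[10];
  std::vector<vec> dxs;
  lstm_backward(w, c.rec, 2, H, dh, g, &dxs);
  for (size_t s = 0; s < dxs.size(); ++s) {
    mat dP = reshape(dxs[s], c.P[s].n_rows, c.P[s].n_cols);
    mat dH = maxpool_back(dP, c.idx[s], c.L[s]);
    mat dZ = dH % relu_grad(c.Z[s]);
    g[0] += c.A[s].t() * dZ;
    g[1] += sum(dZ, 0).t();
  }
}

// ---- shared plumbing ------------------------------------------------------

static std::vector<mat> list_to_mats(const Rcpp::List& init) {
  std::vector<mat> w(init.size());
  for (int i = 0; i < init.size(); ++i)
    w[i] = Rcpp::as<mat>(init[i]);
  return w;
}

static double forward_dispatch(int family, const mat& X,
                               const std::vector<mat>& w,
                               const Rcpp::List& arch, void* cache) {
  const int pool = Rcpp::as<int>(arch["pool"]);
  if (family == FAMILY_CNN) {
    return cnn_forward(X, w, Rcpp::as<int>(arch["k1"]),
                       Rcpp::as<int>(arch["k2"]), pool,
                       static_cast<CnnCache*>(cache));
  } else if (family == FAMILY_LSTM) {
    return lstm_model_forward(X, w, Rcpp::as<int>(arch["lstm_units"]),
                              static_cast<LstmHeadCache*>(cache));
  }
  return hybrid_forward(X, w, Rcpp::as<int>(arch["n_sub"]),
                        Rcpp::as<int>(arch["sub_len"]),
                        Rcpp::as<int>(arch["k1"]), pool,
                        Rcpp::as<int>(arch["lstm_units"]),
                        static_cast<HybridCache*>(cache));
}

static double bce(double p, double y) {
  const double eps = 1e-12;
  double pc = std::min(std::max(p, eps), 1.0 - eps);
  return -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
}

// [[Rcpp::export]]
Rcpp::List cpp_fit(int family, arma::cube X, arma::vec y, Rcpp::List init,
                   Rcpp::List arch, int epochs, int batch_size, double lr,
                   double weight_decay, Rcpp::LogicalVector decay_mask,
                   Rcpp::IntegerMatrix perms) {
  std::vector<mat> w = list_to_mats(init);
  const int n = (int)X.n_slices;
  std::vector<mat> m(w.size()), v(w.size()), grad(w.size());
  for (size_t i = 0; i < w.size(); ++i) {
    m[i] = mat(w[i].n_rows, w[i].n_cols, fill::zeros);
    v[i] = m[i];
    grad[i] = m[i];
  }
  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  int t_adam = 0;
  vec history(epochs, fill::zeros);

  CnnCache ccache;
  LstmHeadCache lcache;
  HybridCache hcache;
  void* cache = (family == FAMILY_CNN) ? (void*)&ccache
              : (family == FAMILY_LSTM) ? (void*)&lcache
                                        : (void*)&hcache;

  for (int e = 0; e < epochs; ++e) {
    double loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int bs = std::min(batch_size, n - start);
      for (size_t i = 0; i < w.size(); ++i) grad[i].zeros();
      for (int b = 0; b < bs; ++b) {
        const int s = perms(e, start + b) - 1;  // 1-based from R
        const mat& Xs = X.slice(s);
        double p = forward_dispatch(family, Xs, w, arch, cache);
        loss += bce(p, y[s]);
        if (family == FAMILY_CNN) {
          cnn_backward(Xs, w, ccache, y[s], Rcpp::as<int>(arch["k1"]),
                       Rcpp::as<int>(arch["k2"]), grad);
        } else if (family == FAMILY_LSTM) {
          lstm_model_backward(w, lcache, y[s],
                              Rcpp::as<int>(arch["lstm_units"]), grad);
        } else {
          hybrid_backward(w, hcache, y[s], Rcpp::as<int>(arch["k1"]),
                          Rcpp::as<int>(arch["lstm_units"]), grad);
        }
      }
      ++t_adam;
      const double corr = lr * std::sqrt(1.0 - std::pow(beta2, t_adam)) /
                          (1.0 - std::pow(beta1, t_adam));
      for (size_t i = 0; i < w.size(); ++i) {
        grad[i] /= bs;
        m[i] = beta1 * m[i] + (1.0 - beta1) * grad[i];
        v[i] = beta2 * v[i] + (1.0 - beta2) * square(grad[i]);
        // decoupled (AdamW-style) weight decay; biases are not decayed
        w[i] -= corr * m[i] / (sqrt(v[i]) + adam_eps);
        if (weight_decay > 0.0 && decay_mask[i])
          w[i] *= (1.0 - lr * weight_decay);
      }
    }
    history(e) = loss / n;
  }

  Rcpp::List out_w(w.size());
  for (size_t i = 0; i < w.size(); ++i) out_w[i] = w[i];
  return Rcpp::List::create(Rcpp::Named("weights") = out_w,
                            Rcpp::Named("history") = history);
}

// Mean loss and analytic gradients over a sample set; used by the tests to
// finite-difference-check the backward passes.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(int family, arma::cube X, arma::vec y,
                         Rcpp::List weights, Rcpp::List arch) {
  std::vector<mat> w = list_to_mats(weights);
  std::vector<mat> grad(w.size());
  for (size_t i = 0; i < w.size(); ++i)
    grad[i] = mat(w[i].n_rows, w[i].n_cols, fill::zeros);
  const int n = (int)X.n_slices;
  double loss = 0.0;
  CnnCache ccache;
  LstmHeadCache lcache;
  HybridCache hcache;
  for (int s = 0; s < n; ++s) {
    const mat& Xs = X.slice(s);
    if (family == FAMILY_CNN) {
      double p = cnn_forward(Xs, w, Rcpp::as<int>(arch["k1"]),
                             Rcpp::as<int>(arch["k2"]),
                             Rcpp::as<int>(arch["pool"]), &ccache);
      loss += bce(p, y[s]);
      cnn_backward(Xs, w, ccache, y[s], Rcpp::as<int>(arch["k1"]),
                   Rcpp::as<int>(arch["k2"]), grad);
    } else if (family == FAMILY_LSTM) {
      double p = lstm_model_forward(Xs, w, Rcpp::as<int>(arch["lstm_units"]),
                                    &lcache);
      loss += bce(p, y[s]);
      lstm_model_backward(w, lcache, y[s],
                          Rcpp::as<int>(arch["lstm_units"]), grad);
    } else {
      double p = hybrid_forward(Xs, w, Rcpp::as<int>(arch["n_sub"]),
                                Rcpp::as<int>(arch["sub_len"]),
                                Rcpp::as<int>(arch["k1"]),
                                Rcpp::as<int>(arch["pool"]),
                                Rcpp::as<int>(arch["lstm_units"]), &hcache);
      loss += bce(p, y[s]);
      hybrid_backward(w, hcache, y[s], Rcpp::as<int>(arch["k1"]),
                      Rcpp::as<int>(arch["lstm_units"]), grad);
    }
  }
  Rcpp::List out_g(grad.size());
  for (size_t i = 0; i < grad.size(); ++i) out_g[i] = grad[i] / n;
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("grad") = out_g);
}

// [[Rcpp::export]]
arma::vec cpp_predict(int family, arma::cube X, Rcpp::List weights,
                      Rcpp::List arch) {
  std::vector<mat> w = list_to_mats(weights);
  vec out((int)X.n_slices);
  for (uword s = 0; s < X.n_slices; ++s)
    out(s) = forward_dispatch(family, X.slice(s), w, arch, nullptr);
  return out;
}
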