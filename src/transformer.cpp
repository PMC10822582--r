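// Small trainable transformer encoder with multi-head self-attention,
// plus the tagging heads (5 linear-softmax classifiers on token embeddings)
// and the linking heads (link + same-tag linear classifiers on concatenated
// token-embedding pairs). Forward and analytic backward passes; gradients
// are verified against finite differences in the test suite.
//
// Parameters live in one flat R numeric vector. All matrix "views" below
// are constructed in place with Armadillo's aux-memory constructors so that
// writes go straight through to the flat vector; they are never copy
// assigned (which would detach them).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LN_EPS = 1e-5;

struct TfSpec {
  int V;   // vocabulary size
  int L;   // maximum sequence length (learned positions)
  int d;   // model width
  int nl;  // encoder layers
  int nh;  // attention heads
  int f;   // feed-forward width
};

static TfSpec spec_from_list(const Rcpp::List& s) {
  TfSpec sp;
  sp.V = Rcpp::as<int>(s["vocab_size"]);
  sp.L = Rcpp::as<int>(s["max_len"]);
  sp.d = Rcpp::as<int>(s["d_model"]);
  sp.nl = Rcpp::as<int>(s["n_layers"]);
  sp.nh = Rcpp::as<int>(s["n_heads"]);
  sp.f = Rcpp::as<int>(s["d_ff"]);
  if (sp.d % sp.nh != 0) Rcpp::stop("d_model must be divisible by n_heads");
  return sp;
}

// sequential-offset cursor over a flat parameter buffer
struct Cursor {
  double* base;
  size_t off;
  double* take(size_t n) { double* p = base + off; off += n; return p; }
};

// layout order below must match the member declaration order (member
// initializers run in declaration order)
struct LayerParams {
  mat Wq; rowvec bq; mat Wk; rowvec bk; mat Wv; rowvec bv; mat Wo; rowvec bo;
  rowvec g1, be1;
  mat W1; rowvec b1; mat W2; rowvec b2;
  rowvec g2, be2;
  LayerParams(Cursor& c, int d, int f)
    : Wq(c.take((size_t)d * d), d, d, false, true), bq(c.take(d), d, false, true),
      Wk(c.take((size_t)d * d), d, d, false, true), bk(c.take(d), d, false, true),
      Wv(c.take((size_t)d * d), d, d, false, true), bv(c.take(d), d, false, true),
      Wo(c.take((size_t)d * d), d, d, false, true), bo(c.take(d), d, false, true),
      g1(c.take(d), d, false, true), be1(c.take(d), d, false, true),
      W1(c.take((size_t)d * f), d, f, false, true), b1(c.take(f), f, false, true),
      W2(c.take((size_t)f * d), f, d, false, true), b2(c.take(d), d, false, true),
      g2(c.take(d), d, false, true), be2(c.take(d), d, false, true) {}
};

struct EncoderParams {
  mat E, P;
  std::vector<LayerParams> layers;
  EncoderParams(Cursor& c, const TfSpec& sp)
    : E(c.take((size_t)sp.V * sp.d), sp.V, sp.d, false, true),
      P(c.take((size_t)sp.L * sp.d), sp.L, sp.d, false, true) {
    layers.reserve(sp.nl);
    for (int l = 0; l < sp.nl; ++l) layers.emplace_back(c, sp.d, sp.f);
  }
};

static size_t layer_count(const TfSpec& sp) {
  size_t d = sp.d, f = sp.f;
  return 4 * (d * d + d) + 2 * d + d * f + f + f * d + d + 2 * d;
}

static size_t encoder_count(const TfSpec& sp) {
  return (size_t)sp.V * sp.d + (size_t)sp.L * sp.d + (size_t)sp.nl * layer_count(sp);
}

struct HeadParams {
  std::vector<mat> W;
  std::vector<rowvec> b;
  HeadParams(Cursor& c, int d, const Rcpp::IntegerVector& sizes) {
    W.reserve(sizes.size());
    b.reserve(sizes.size());
    for (int h = 0; h < sizes.size(); ++h) {
      int C = sizes[h];
      W.emplace_back(c.take((size_t)d * C), d, C, false, true);
      b.emplace_back(c.take(C), C, false, true);
    }
  }
};

struct PairHeads {
  rowvec Wl; double* bl; rowvec Ws; double* bs;
  PairHeads(Cursor& c, int d)
    : Wl(c.take(2 * d), 2 * d, false, true), bl(c.take(1)),
      Ws(c.take(2 * d), 2 * d, false, true), bs(c.take(1)) {}
};

struct LayerCache {
  mat Xin, Q, K, Vv, A, xhat1, X1, Hpre, xhat2, X2;
  vec inv1, inv2;
  cube Ph; // softmax attention matrices, one slice per head
};

struct Cache {
  uvec ids0; // 0-based token ids
  std::vector<LayerCache> layers;
};

static void layer_norm_fwd(const mat& x, const rowvec& g, const rowvec& b,
                           mat& xhat, vec& inv, mat& y) {
  int n = x.n_rows;
  xhat.set_size(n, x.n_cols);
  inv.set_size(n);
  y.set_size(n, x.n_cols);
  for (int i = 0; i < n; ++i) {
    double mu = mean(x.row(i));
    double va = mean(square(x.row(i) - mu));
    double iv = 1.0 / std::sqrt(va + LN_EPS);
    inv(i) = iv;
    xhat.row(i) = (x.row(i) - mu) * iv;
    y.row(i) = xhat.row(i) % g + b;
  }
}

// backward through layer norm; accumulates dg, db; returns dx
static mat layer_norm_bwd(const mat& dy, const mat& xhat, const vec& inv,
                          const rowvec& g, rowvec& dg, rowvec& db) {
  int n = dy.n_rows;
  mat dx(n, dy.n_cols);
  for (int i = 0; i < n; ++i) {
    dg += dy.row(i) % xhat.row(i);
    db += dy.row(i);
    rowvec dxh = dy.row(i) % g;
    double m1 = mean(dxh);
    double m2 = mean(dxh % xhat.row(i));
    dx.row(i) = inv(i) * (dxh - m1 - xhat.row(i) * m2);
  }
  return dx;
}

// forward pass; fills cache, returns final embeddings (n x d)
static mat encoder_forward(const EncoderParams& p, const TfSpec& sp,
                           const Rcpp::IntegerVector& ids, Cache& cache) {
  int n = ids.size();
  if (n == 0) Rcpp::stop("empty token sequence");
  if (n > sp.L) Rcpp::stop("sequence of %d tokens exceeds max_len %d", n, sp.L);
  cache.ids0.set_size(n);
  mat X(n, sp.d);
  for (int t = 0; t < n; ++t) {
    int id = ids[t] - 1;
    if (id < 0 || id >= sp.V) Rcpp::stop("token id out of range");
    cache.ids0(t) = id;
    X.row(t) = p.E.row(id) + p.P.row(t);
  }
  int dk = sp.d / sp.nh;
  double scale = 1.0 / std::sqrt((double)dk);
  cache.layers.resize(sp.nl);
  for (int l = 0; l < sp.nl; ++l) {
    const LayerParams& lp = p.layers[l];
    LayerCache& lc = cache.layers[l];
    lc.Xin = X;
    lc.Q = X * lp.Wq; lc.Q.each_row() += lp.bq;
    lc.K = X * lp.Wk; lc.K.each_row() += lp.bk;
    lc.Vv = X * lp.Wv; lc.Vv.each_row() += lp.bv;
    lc.A.set_size(n, sp.d);
    lc.Ph.set_size(n, n, sp.nh);
    for (int h = 0; h < sp.nh; ++h) {
      mat Qh = lc.Q.cols(h * dk, (h + 1) * dk - 1);
      mat Kh = lc.K.cols(h * dk, (h + 1) * dk - 1);
      mat Vh = lc.Vv.cols(h * dk, (h + 1) * dk - 1);
      mat S = Qh * Kh.t() * scale;
      for (int i = 0; i < n; ++i) {
        rowvec r = S.row(i) - S.row(i).max();
        rowvec e = exp(r);
        lc.Ph.slice(h).row(i) = e / accu(e);
      }
      lc.A.cols(h * dk, (h + 1) * dk - 1) = lc.Ph.slice(h) * Vh;
    }
    mat O = lc.A * lp.Wo; O.each_row() += lp.bo;
    mat res1 = lc.Xin + O;
    layer_norm_fwd(res1, lp.g1, lp.be1, lc.xhat1, lc.inv1, lc.X1);
    lc.Hpre = lc.X1 * lp.W1; lc.Hpre.each_row() += lp.b1;
    mat H = clamp(lc.Hpre, 0.0, datum::inf); // relu
    mat F = H * lp.W2; F.each_row() += lp.b2;
    mat res2 = lc.X1 + F;
    layer_norm_fwd(res2, lp.g2, lp.be2, lc.xhat2, lc.inv2, lc.X2);
    X = lc.X2;
  }
  return X;
}

// backward pass: dX is the gradient wrt the encoder output; accumulates
// parameter gradients into g (views over the flat gradient vector)
static void encoder_backward(const EncoderParams& p, EncoderParams& g,
                             const TfSpec& sp, const Cache& cache, mat dX) {
  int dk = sp.d / sp.nh;
  double scale = 1.0 / std::sqrt((double)dk);
  for (int l = sp.nl - 1; l >= 0; --l) {
    const LayerParams& lp = p.layers[l];
    LayerParams& lg = g.layers[l];
    const LayerCache& lc = cache.layers[l];
    int n = lc.Xin.n_rows;

    mat dres2 = layer_norm_bwd(dX, lc.xhat2, lc.inv2, lp.g2, lg.g2, lg.be2);
    mat dX1 = dres2; // residual branch
    const mat& dF = dres2;
    mat H = clamp(lc.Hpre, 0.0, datum::inf);
    lg.W2 += H.t() * dF;
    lg.b2 += sum(dF, 0);
    mat dH = dF * lp.W2.t();
    mat dHpre = dH % conv_to<mat>::from(lc.Hpre > 0.0);
    lg.W1 += lc.X1.t() * dHpre;
    lg.b1 += sum(dHpre, 0);
    dX1 += dHpre * lp.W1.t();

    mat dres1 = layer_norm_bwd(dX1, lc.xhat1, lc.inv1, lp.g1, lg.g1, lg.be1);
    mat dXin = dres1; // residual branch
    const mat& dO = dres1;
    lg.Wo += lc.A.t() * dO;
    lg.bo += sum(dO, 0);
    mat dA = dO * lp.Wo.t();

    mat dQ(n, sp.d, fill::zeros), dK(n, sp.d, fill::zeros), dV(n, sp.d, fill::zeros);
    for (int h = 0; h < sp.nh; ++h) {
      mat Qh = lc.Q.cols(h * dk, (h + 1) * dk - 1);
      mat Kh = lc.K.cols(h * dk, (h + 1) * dk - 1);
      mat Vh = lc.Vv.cols(h * dk, (h + 1) * dk - 1);
      mat dAh = dA.cols(h * dk, (h + 1) * dk - 1);
      const mat& Ph = lc.Ph.slice(h);
      dV.cols(h * dk, (h + 1) * dk - 1) = Ph.t() * dAh;
      mat dPh = dAh * Vh.t();
      vec rs = sum(dPh % Ph, 1);
      mat dS = Ph % (dPh.each_col() - rs);
      dQ.cols(h * dk, (h + 1) * dk - 1) = dS * Kh * scale;
      dK.cols(h * dk, (h + 1) * dk - 1) = dS.t() * Qh * scale;
    }
    lg.Wq += lc.Xin.t() * dQ; lg.bq += sum(dQ, 0);
    lg.Wk += lc.Xin.t() * dK; lg.bk += sum(dK, 0);
    lg.Wv += lc.Xin.t() * dV; lg.bv += sum(dV, 0);
    dXin += dQ * lp.Wq.t() + dK * lp.Wk.t() + dV * lp.Wv.t();
    dX = dXin;
  }
  for (size_t t = 0; t < cache.ids0.n_elem; ++t) {
    g.E.row(cache.ids0(t)) += dX.row(t);
    g.P.row(t) += dX.row(t);
  }
}

// ---------------------------------------------------------------------------
// exported: parameter bookkeeping


static void check_theta(const Rcpp::NumericVector& theta, size_t expected) {
  if ((size_t)theta.size() != expected)
    Rcpp::stop("parameter vector has %d values, expected %d",
               (int)theta.size(), (int)expected);
}

// [[Rcpp::export(name = "cpp_encoder_param_count")]]
double cpp_encoder_param_count(Rcpp::List spec) {
  return (double)encoder_count(spec_from_list(spec));
}

// [[Rcpp::export(name = "cpp_tagger_param_count")]]
double cpp_tagger_param_count(Rcpp::List spec, Rcpp::IntegerVector head_sizes) {
  TfSpec sp = spec_from_list(spec);
  size_t n = encoder_count(sp);
  for (int h = 0; h < head_sizes.size(); ++h) {
    n += (size_t)sp.d * head_sizes[h] + head_sizes[h];
  }
  return (double)n;
}

// [[Rcpp::export(name = "cpp_linker_param_count")]]
double cpp_linker_param_count(Rcpp::List spec) {
  TfSpec sp = spec_from_list(spec);
  return (double)(encoder_count(sp) + 2 * (2 * sp.d + 1));
}

// ---------------------------------------------------------------------------
// exported: plain encoder forward (token embeddings)

// [[Rcpp::export(name = "cpp_encode")]]
arma::mat cpp_encode(Rcpp::NumericVector theta, Rcpp::List spec,
                     Rcpp::IntegerVector ids) {
  TfSpec sp = spec_from_list(spec);
  // a full model parameter vector (encoder + heads) is acceptable here:
  // only the leading encoder block is read
  if ((size_t)theta.size() < encoder_count(sp))
    Rcpp::stop("parameter vector has %d values, need at least %d",
               (int)theta.size(), (int)encoder_count(sp));
  Cursor c{REAL(theta), 0};
  EncoderParams p(c, sp);
  Cache cache;
  return encoder_forward(p, sp, ids, cache);
}

// ---------------------------------------------------------------------------
// tagging model

// [[Rcpp::export(name = "cpp_tagger_forward")]]
Rcpp::List cpp_tagger_forward(Rcpp::NumericVector theta, Rcpp::List spec,
                              Rcpp::IntegerVector head_sizes,
                              Rcpp::IntegerVector ids) {
  TfSpec sp = spec_from_list(spec);
  size_t want = encoder_count(sp);
  for (int h = 0; h < head_sizes.size(); ++h)
    want += (size_t)sp.d * head_sizes[h] + head_sizes[h];
  check_theta(theta, want);
  Cursor c{REAL(theta), 0};
  EncoderParams p(c, sp);
  HeadParams heads(c, sp.d, head_sizes);
  Cache cache;
  mat X = encoder_forward(p, sp, ids, cache);
  Rcpp::List out(head_sizes.size());
  for (int h = 0; h < head_sizes.size(); ++h) {
    mat Z = X * heads.W[h]; Z.each_row() += heads.b[h];
    mat Pm(Z.n_rows, Z.n_cols);
    for (size_t i = 0; i < Z.n_rows; ++i) {
      rowvec e = exp(Z.row(i) - Z.row(i).max());
      Pm.row(i) = e / accu(e);
    }
    out[h] = Pm;
  }
  return out;
}

// labels: list of 1-based class-id integer vectors, one per head
// weights: list of per-class weight vectors, one per head
// head_scales: multiplier per head (0 disables a head, e.g. ablations)
// [[Rcpp::export(name = "cpp_tagger_loss_grad")]]
Rcpp::List cpp_tagger_loss_grad(Rcpp::NumericVector theta, Rcpp::List spec,
                                Rcpp::IntegerVector head_sizes,
                                Rcpp::IntegerVector ids, Rcpp::List labels,
                                Rcpp::List weights,
                                Rcpp::NumericVector head_scales,
                                bool want_grad = true) {
  TfSpec sp = spec_from_list(spec);
  size_t want = encoder_count(sp);
  for (int h = 0; h < head_sizes.size(); ++h)
    want += (size_t)sp.d * head_sizes[h] + head_sizes[h];
  check_theta(theta, want);
  Cursor c{REAL(theta), 0};
  EncoderParams p(c, sp);
  HeadParams heads(c, sp.d, head_sizes);
  Cache cache;
  mat X = encoder_forward(p, sp, ids, cache);
  int n = X.n_rows;

  Rcpp::NumericVector grad(theta.size());
  Cursor gc{REAL(grad), 0};
  EncoderParams g(gc, sp);
  HeadParams gheads(gc, sp.d, head_sizes);

  mat dX(n, sp.d, fill::zeros);
  double loss = 0.0;
  for (int h = 0; h < head_sizes.size(); ++h) {
    double sc = head_scales[h];
    if (sc == 0.0) continue;
    Rcpp::IntegerVector y = labels[h];
    Rcpp::NumericVector w = weights[h];
    if (y.size() != n) Rcpp::stop("labels/token length mismatch for head %d", h + 1);
    mat Z = X * heads.W[h]; Z.each_row() += heads.b[h];
    for (int i = 0; i < n; ++i) {
      rowvec e = exp(Z.row(i) - Z.row(i).max());
      rowvec pr = e / accu(e);
      int yi = y[i] - 1;
      if (yi < 0 || yi >= (int)pr.n_elem) Rcpp::stop("label id out of range");
      double wy = w[yi];
      loss += -sc * wy * std::log(std::max(pr(yi), 1e-300));
      if (want_grad) {
        rowvec dz = pr * (sc * wy);
        dz(yi) -= sc * wy;
        gheads.W[h] += X.row(i).t() * dz;
        gheads.b[h] += dz;
        dX.row(i) += dz * heads.W[h].t();
      }
    }
  }
  if (want_grad) encoder_backward(p, g, sp, cache, dX);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// ---------------------------------------------------------------------------
// linking model

// [[Rcpp::export(name = "cpp_linker_forward")]]
arma::mat cpp_linker_forward(Rcpp::NumericVector theta, Rcpp::List spec,
                             Rcpp::IntegerVector ids,
                             Rcpp::IntegerVector pi, Rcpp::IntegerVector pj) {
  TfSpec sp = spec_from_list(spec);
  check_theta(theta, encoder_count(sp) + 2 * (2 * (size_t)sp.d + 1));
  Cursor c{REAL(theta), 0};
  EncoderParams p(c, sp);
  PairHeads ph(c, sp.d);
  Cache cache;
  mat X = encoder_forward(p, sp, ids, cache);
  int np = pi.size();
  mat out(np, 2);
  for (int k = 0; k < np; ++k) {
    rowvec x = join_rows(X.row(pi[k] - 1), X.row(pj[k] - 1));
    out(k, 0) = 1.0 / (1.0 + std::exp(-(dot(ph.Wl, x) + *ph.bl)));
    out(k, 1) = 1.0 / (1.0 + std::exp(-(dot(ph.Ws, x) + *ph.bs)));
  }
  return out;
}

// wlink/wsame: per-pair weights (class balancing applied by caller)
// lambda: weight of the auxiliary same-tag objective
// [[Rcpp::export(name = "cpp_linker_loss_grad")]]
Rcpp::List cpp_linker_loss_grad(Rcpp::NumericVector theta, Rcpp::List spec,
                                Rcpp::IntegerVector ids,
                                Rcpp::IntegerVector pi, Rcpp::IntegerVector pj,
                                Rcpp::NumericVector ylink,
                                Rcpp::NumericVector ysame,
                                Rcpp::NumericVector wlink,
                                Rcpp::NumericVector wsame,
                                double lambda, bool want_grad = true) {
  TfSpec sp = spec_from_list(spec);
  check_theta(theta, encoder_count(sp) + 2 * (2 * (size_t)sp.d + 1));
  Cursor c{REAL(theta), 0};
  EncoderParams p(c, sp);
  PairHeads ph(c, sp.d);
  Cache cache;
  mat X = encoder_forward(p, sp, ids, cache);
  int n = X.n_rows, d = sp.d;

  Rcpp::NumericVector grad(theta.size());
  Cursor gc{REAL(grad), 0};
  EncoderParams g(gc, sp);
  PairHeads gh(gc, d);

  mat dX(n, d, fill::zeros);
  double loss = 0.0;
  int np = pi.size();
  uvec ia(np), ib(np);
  for (int k = 0; k < np; ++k) {
    int a = pi[k] - 1, b = pj[k] - 1;
    if (a < 0 || b < 0 || a >= n || b >= n) Rcpp::stop("pair index out of range");
    ia[k] = a; ib[k] = b;
  }
  mat Xa = X.rows(ia), Xb = X.rows(ib);          // np x d each
  vec Wla = ph.Wl.cols(0, d - 1).t(), Wlb = ph.Wl.cols(d, 2 * d - 1).t();
  vec Wsa = ph.Ws.cols(0, d - 1).t(), Wsb = ph.Ws.cols(d, 2 * d - 1).t();
  vec yl(ylink.begin(), np, false), wl(wlink.begin(), np, false);
  vec zl = Xa * Wla + Xb * Wlb + *ph.bl;
  vec pl = 1.0 / (1.0 + exp(-zl));
  loss += accu(-wl % (yl % log(clamp(pl, 1e-300, 1.0)) +
                      (1 - yl) % log(clamp(1 - pl, 1e-300, 1.0))));
  vec dzl, dzs;
  if (want_grad) {
    dzl = wl % (pl - yl);
    gh.Wl += join_rows(dzl.t() * Xa, dzl.t() * Xb);
    *gh.bl += accu(dzl);
  }
  if (lambda != 0.0) {
    vec ys(ysame.begin(), np, false);
    vec ws = lambda * vec(wsame.begin(), np, false);
    vec zs = Xa * Wsa + Xb * Wsb + *ph.bs;
    vec psv = 1.0 / (1.0 + exp(-zs));
    loss += accu(-ws % (ys % log(clamp(psv, 1e-300, 1.0)) +
                        (1 - ys) % log(clamp(1 - psv, 1e-300, 1.0))));
    if (want_grad) {
      dzs = ws % (psv - ys);
      gh.Ws += join_rows(dzs.t() * Xa, dzs.t() * Xb);
      *gh.bs += accu(dzs);
    }
  }
  if (want_grad) {
    // scatter-add the per-pair input gradients back onto the tokens
    for (int k = 0; k < np; ++k) {
      dX.row(ia[k]) += dzl[k] * Wla.t();
      dX.row(ib[k]) += dzl[k] * Wlb.t();
      if (lambda != 0.0) {
        dX.row(ia[k]) += dzs[k] * Wsa.t();
        dX.row(ib[k]) += dzs[k] * Wsb.t();
      }
    }
    encoder_backward(p, g, sp, cache, dX);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// ---------------------------------------------------------------------------
// Adam with global-norm gradient clipping; updates theta, m and v in place
// (the caller owns the buffers and passes them back every step)

// [[Rcpp::export(name = "cpp_adam_step")]]
double cpp_adam_step(Rcpp::NumericVector theta, Rcpp::NumericVector grad,
                     Rcpp::NumericVector m, Rcpp::NumericVector v, int t,
                     double lr, double beta1, double beta2, double eps,
                     double clip) {
  R_xlen_t n = theta.size();
  if (grad.size() != n || m.size() != n || v.size() != n)
    Rcpp::stop("length mismatch in adam step");
  double *th = REAL(theta), *g = REAL(grad), *mm = REAL(m), *vv = REAL(v);
  double sq = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) sq += g[i] * g[i];
  double scale = 1.0;
  double gn = std::sqrt(sq);
  if (R_finite(clip) && gn > clip) scale = clip / gn;
  double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i] * scale;
    mm[i] = beta1 * mm[i] + (1.0 - beta1) * gi;
    vv[i] = beta2 * vv[i] + (1.0 - beta2) * gi * gi;
    th[i] -= lr * (mm[i] / c1) / (std::sqrt(vv[i] / c2) + eps);
  }
  return gn;
}
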