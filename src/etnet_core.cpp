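// Batched forward/backward pass of the two-branch CNN + Transformer-encoder
// classifier. Mirrors the reference R implementation (R/model.R) exactly;
// the two engines are cross-checked in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uword;

namespace {

struct Dims {
  int B, L, k, pad, P, Tm, T2, C, D, H, dqk, dv, dkh, dvh, ffn, layers;
  bool tie_conv;
};

Dims read_dims(const List& dims) {
  Dims d;
  d.B = dims["B"]; d.L = dims["L"]; d.k = dims["k"]; d.P = dims["P"];
  d.C = dims["C"]; d.D = dims["D"]; d.H = dims["H"];
  d.dqk = dims["dqk"]; d.dv = dims["dv"]; d.ffn = dims["ffn"];
  d.layers = dims["layers"]; d.tie_conv = dims["tie_conv"];
  d.pad = (d.k - 1) / 2;
  d.Tm = d.L / d.P;
  d.T2 = 2 * d.Tm;
  d.dkh = d.dqk / d.H;
  d.dvh = d.dv / d.H;
  return d;
}

std::string enc_name(int l, const char* suffix) {
  return "enc" + std::to_string(l + 1) + "_" + suffix;
}

mat relu_mask(mat& x) { // rectify in place, return the 0/1 mask
  mat m = arma::conv_to<mat>::from(x > 0);
  x %= m;
  return m;
}

mat dropout_mask(int n, int m, double p) {
  mat mk(n, m);
  double scale = 1.0 / (1.0 - p);
  for (uword j = 0; j < mk.n_cols; ++j)
    for (uword i = 0; i < mk.n_rows; ++i)
      mk(i, j) = (unif_rand() >= p) ? scale : 0.0;
  return mk;
}

struct ConvCache {
  mat IC, cmask, pool, M, mmask;
  arma::umat amax;
};

// one branch: im2col conv -> ReLU -> max-pool -> single-layer MLP -> tokens
ConvCache conv_fwd(const Dims& d, const mat& X, const mat& Wc, const rowvec& bc,
                   const mat& Wm, const rowvec& bm) {
  ConvCache c;
  c.IC.zeros(d.B * d.L, 4 * d.k);
  for (int j = 0; j < d.k; ++j) {
    int off = j - d.pad;
    int t_lo = std::max(0, -off);
    int t_hi = std::min(d.L - 1, d.L - 1 - off);
    if (t_lo > t_hi) continue;
    for (int b = 0; b < d.B; ++b) {
      int base = b * d.L;
      c.IC.submat(base + t_lo, 4 * j, base + t_hi, 4 * j + 3) =
        X.rows(base + t_lo + off, base + t_hi + off);
    }
  }
  mat Hc = c.IC * Wc;
  Hc.each_row() += bc;
  c.cmask = relu_mask(Hc);
  int nt = d.B * d.Tm;
  c.pool.set_size(nt, d.C);
  c.amax.set_size(nt, d.C);
  for (int i = 0; i < nt; ++i) {
    for (int ch = 0; ch < d.C; ++ch) {
      double best = Hc(i * d.P, ch);
      int arg = 0;
      for (int j = 1; j < d.P; ++j) {
        double hv = Hc(i * d.P + j, ch);
        if (hv > best) { best = hv; arg = j; }
      }
      c.pool(i, ch) = best;
      c.amax(i, ch) = arg;
    }
  }
  c.M = c.pool * Wm;
  c.M.each_row() += bm;
  c.mmask = relu_mask(c.M);
  return c;
}

struct ConvGrads {
  mat dWc, dWm, dX;
  rowvec dbc, dbm;
  bool has_dX = false;
};

ConvGrads conv_bwd(const Dims& d, const ConvCache& c, const mat& dM,
                   const mat& Wc, const mat& Wm, bool want_input_grad) {
  ConvGrads g;
  mat dMpre = dM % c.mmask;
  g.dWm = c.pool.t() * dMpre;
  g.dbm = arma::sum(dMpre, 0);
  mat dpool = dMpre * Wm.t();
  mat dH(d.B * d.L, d.C, arma::fill::zeros);
  int nt = d.B * d.Tm;
  for (int i = 0; i < nt; ++i)
    for (int ch = 0; ch < d.C; ++ch)
      dH(i * d.P + c.amax(i, ch), ch) = dpool(i, ch);
  dH %= c.cmask;
  g.dWc = c.IC.t() * dH;
  g.dbc = arma::sum(dH, 0);
  if (want_input_grad) {
    mat dIC = dH * Wc.t();
    g.dX.zeros(d.B * d.L, 4);
    for (int j = 0; j < d.k; ++j) {
      int off = j - d.pad;
      int t_lo = std::max(0, -off);
      int t_hi = std::min(d.L - 1, d.L - 1 - off);
      if (t_lo > t_hi) continue;
      for (int b = 0; b < d.B; ++b) {
        int base = b * d.L;
        g.dX.rows(base + t_lo + off, base + t_hi + off) +=
          dIC.submat(base + t_lo, 4 * j, base + t_hi, 4 * j + 3);
      }
    }
    g.has_dX = true;
  }
  return g;
}

struct LayerCache {
  mat Xin, Q, K, V, O, m1, m2, xhat1, xhat2, X1, F1, fmask;
  vec istd1, istd2;
  arma::cube A; // T2 x T2 x (B*H)
  bool has_m1 = false, has_m2 = false;
};

void layernorm_fwd(const mat& x, const vec& gvec, const vec& bvec,
                   mat& y, mat& xhat, vec& istd) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  istd = 1.0 / arma::sqrt(arma::mean(arma::square(xc), 1) + 1e-5);
  xhat = xc.each_col() % istd;
  y = xhat.each_row() % gvec.t();
  y.each_row() += bvec.t();
}

mat layernorm_bwd(const mat& dy, const mat& xhat, const vec& istd,
                  const vec& gvec, vec& dg, vec& db) {
  dg = (arma::sum(dy % xhat, 0)).t();
  db = (arma::sum(dy, 0)).t();
  mat dxhat = dy.each_row() % gvec.t();
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= istd;
  return dx;
}

} // namespace

// [[Rcpp::export]]
List cpp_batch(const List& params, const List& dims_in, const arma::mat& Xl,
               const arma::mat& Xr, const Nullable<NumericVector>& y_in,
               double dropout, bool train, bool want_grads,
               bool want_input_grad) {
  Dims d = read_dims(dims_in);
  const mat Wc = params["conv_w"];
  const rowvec bc = as<vec>(params["conv_b"]).t();
  const mat Wm = params["mlp_w"];
  const rowvec bm = as<vec>(params["mlp_b"]).t();
  mat Wc_r, dummy;
  rowvec bc_r;
  if (!d.tie_conv) {
    Wc_r = as<mat>(params["conv_w_r"]);
    bc_r = as<vec>(params["conv_b_r"]).t();
  }

  ConvCache cl = conv_fwd(d, Xl, Wc, bc, Wm, bm);
  ConvCache cr = d.tie_conv ? conv_fwd(d, Xr, Wc, bc, Wm, bm)
                            : conv_fwd(d, Xr, Wc_r, bc_r, Wm, bm);

  mat X0(d.B * d.T2, d.D);
  for (int b = 0; b < d.B; ++b) {
    X0.rows(b * d.T2, b * d.T2 + d.Tm - 1) =
      cl.M.rows(b * d.Tm, (b + 1) * d.Tm - 1);
    X0.rows(b * d.T2 + d.Tm, (b + 1) * d.T2 - 1) =
      cr.M.rows(b * d.Tm, (b + 1) * d.Tm - 1);
  }

  std::vector<LayerCache> lcs(d.layers);
  mat Xin = X0;
  double sq = std::sqrt((double)d.dkh);
  for (int l = 0; l < d.layers; ++l) {
    LayerCache& lc = lcs[l];
    lc.Xin = Xin;
    const mat Wq = params[enc_name(l, "wq")], Wk = params[enc_name(l, "wk")],
              Wv = params[enc_name(l, "wv")], Wo = params[enc_name(l, "wo")];
    const rowvec bq = as<vec>(params[enc_name(l, "bq")]).t(),
                 bk = as<vec>(params[enc_name(l, "bk")]).t(),
                 bv = as<vec>(params[enc_name(l, "bv")]).t(),
                 bo = as<vec>(params[enc_name(l, "bo")]).t();
    const mat rel = params[enc_name(l, "rel")];
    lc.Q = Xin * Wq; lc.Q.each_row() += bq;
    lc.K = Xin * Wk; lc.K.each_row() += bk;
    lc.V = Xin * Wv; lc.V.each_row() += bv;
    // relative-position bias matrices per head
    std::vector<mat> relmats(d.H);
    for (int h = 0; h < d.H; ++h) {
      mat bmat(d.T2, d.T2);
      for (int t = 0; t < d.T2; ++t)
        for (int s = 0; s < d.T2; ++s)
          bmat(t, s) = rel(h, s - t + d.T2 - 1);
      relmats[h] = bmat;
    }
    lc.O.set_size(d.B * d.T2, d.dv);
    lc.A.set_size(d.T2, d.T2, d.B * d.H);
    for (int b = 0; b < d.B; ++b) {
      int r0 = b * d.T2, r1 = (b + 1) * d.T2 - 1;
      for (int h = 0; h < d.H; ++h) {
        int q0 = h * d.dkh, q1 = (h + 1) * d.dkh - 1;
        int v0 = h * d.dvh, v1 = (h + 1) * d.dvh - 1;
        mat S = lc.Q.submat(r0, q0, r1, q1) *
                lc.K.submat(r0, q0, r1, q1).t() / sq + relmats[h];
        S.each_col() -= arma::max(S, 1);
        mat A = arma::exp(S);
        A.each_col() /= arma::sum(A, 1);
        lc.A.slice(b * d.H + h) = A;
        lc.O.submat(r0, v0, r1, v1) = A * lc.V.submat(r0, v0, r1, v1);
      }
    }
    mat AO = lc.O * Wo;
    AO.each_row() += bo;
    if (train && dropout > 0) {
      lc.m1 = dropout_mask(AO.n_rows, AO.n_cols, dropout);
      lc.has_m1 = true;
      AO %= lc.m1;
    }
    mat R1 = Xin + AO;
    layernorm_fwd(R1, params[enc_name(l, "ln1_g")], params[enc_name(l, "ln1_b")],
                  lc.X1, lc.xhat1, lc.istd1);
    const mat Wf1 = params[enc_name(l, "ff_w1")], Wf2 = params[enc_name(l, "ff_w2")];
    const rowvec bf1 = as<vec>(params[enc_name(l, "ff_b1")]).t(),
                 bf2 = as<vec>(params[enc_name(l, "ff_b2")]).t();
    lc.F1 = lc.X1 * Wf1;
    lc.F1.each_row() += bf1;
    lc.fmask = relu_mask(lc.F1);
    mat F2 = lc.F1 * Wf2;
    F2.each_row() += bf2;
    if (train && dropout > 0) {
      lc.m2 = dropout_mask(F2.n_rows, F2.n_cols, dropout);
      lc.has_m2 = true;
      F2 %= lc.m2;
    }
    mat R2 = lc.X1 + F2;
    mat X2;
    layernorm_fwd(R2, params[enc_name(l, "ln2_g")], params[enc_name(l, "ln2_b")],
                  X2, lc.xhat2, lc.istd2);
    Xin = X2;
  }
  mat X2 = Xin;

  // prediction heads: mean-pool per sample per side
  mat pl(d.B, d.D), pr(d.B, d.D);
  for (int b = 0; b < d.B; ++b) {
    pl.row(b) = arma::mean(X2.rows(b * d.T2, b * d.T2 + d.Tm - 1), 0);
    pr.row(b) = arma::mean(X2.rows(b * d.T2 + d.Tm, (b + 1) * d.T2 - 1), 0);
  }
  const mat Whl = params["head_l_w"], Whr = params["head_r_w"];
  const rowvec bhl = as<vec>(params["head_l_b"]).t(),
               bhr = as<vec>(params["head_r_b"]).t();
  const vec vhl = params["head_l_v"], vhr = params["head_r_v"];
  double chl = as<double>(params["head_l_c"]),
         chr_ = as<double>(params["head_r_c"]);
  mat Hl = pl * Whl; Hl.each_row() += bhl;
  mat hlmask = relu_mask(Hl);
  vec zl = Hl * vhl + chl;
  mat Hr = pr * Whr; Hr.each_row() += bhr;
  mat hrmask = relu_mask(Hr);
  vec zr = Hr * vhr + chr_;
  vec logit = (zl + zr) / 2.0;
  vec prob = 1.0 / (1.0 + arma::exp(-logit));

  List out;
  out["prob"] = NumericVector(prob.begin(), prob.end());
  double loss = NA_REAL;
  vec dlogit;
  if (y_in.isNotNull()) {
    vec y = as<vec>(y_in.get());
    double eps = 1e-12;
    loss = -arma::mean(y % arma::log(prob + eps) +
                       (1.0 - y) % arma::log(1.0 - prob + eps));
    dlogit = (prob - y) / (double)d.B;
  } else {
    dlogit = vec(d.B, arma::fill::ones); // gradient of the summed logit
  }
  out["loss"] = loss;
  if (!want_grads && !want_input_grad) return out;

  List g;
  vec dz = dlogit / 2.0;
  g["head_l_v"] = Hl.t() * dz;
  g["head_l_c"] = arma::accu(dz);
  mat dHl = (dz * vhl.t()) % hlmask;
  g["head_l_w"] = pl.t() * dHl;
  g["head_l_b"] = vec((arma::sum(dHl, 0)).t());
  mat dpl = dHl * Whl.t();
  g["head_r_v"] = Hr.t() * dz;
  g["head_r_c"] = arma::accu(dz);
  mat dHr = (dz * vhr.t()) % hrmask;
  g["head_r_w"] = pr.t() * dHr;
  g["head_r_b"] = vec((arma::sum(dHr, 0)).t());
  mat dpr = dHr * Whr.t();

  mat dX(d.B * d.T2, d.D, arma::fill::zeros);
  for (int b = 0; b < d.B; ++b) {
    for (int t = 0; t < d.Tm; ++t) {
      dX.row(b * d.T2 + t) = dpl.row(b) / (double)d.Tm;
      dX.row(b * d.T2 + d.Tm + t) = dpr.row(b) / (double)d.Tm;
    }
  }

  for (int l = d.layers - 1; l >= 0; --l) {
    LayerCache& lc = lcs[l];
    const mat Wq = params[enc_name(l, "wq")], Wk = params[enc_name(l, "wk")],
              Wv = params[enc_name(l, "wv")], Wo = params[enc_name(l, "wo")];
    const mat Wf1 = params[enc_name(l, "ff_w1")], Wf2 = params[enc_name(l, "ff_w2")];
    const vec ln1g = params[enc_name(l, "ln1_g")], ln2g = params[enc_name(l, "ln2_g")];
    vec dg, db;
    mat dR2 = layernorm_bwd(dX, lc.xhat2, lc.istd2, ln2g, dg, db);
    g[enc_name(l, "ln2_g")] = dg;
    g[enc_name(l, "ln2_b")] = db;
    mat dF2 = lc.has_m2 ? mat(dR2 % lc.m2) : dR2;
    g[enc_name(l, "ff_w2")] = lc.F1.t() * dF2;
    g[enc_name(l, "ff_b2")] = vec((arma::sum(dF2, 0)).t());
    mat dF1 = (dF2 * Wf2.t()) % lc.fmask;
    g[enc_name(l, "ff_w1")] = lc.X1.t() * dF1;
    g[enc_name(l, "ff_b1")] = vec((arma::sum(dF1, 0)).t());
    mat dX1 = dR2 + dF1 * Wf1.t();
    mat dR1 = layernorm_bwd(dX1, lc.xhat1, lc.istd1, ln1g, dg, db);
    g[enc_name(l, "ln1_g")] = dg;
    g[enc_name(l, "ln1_b")] = db;
    mat dAO = lc.has_m1 ? mat(dR1 % lc.m1) : dR1;
    g[enc_name(l, "wo")] = lc.O.t() * dAO;
    g[enc_name(l, "bo")] = vec((arma::sum(dAO, 0)).t());
    mat dO = dAO * Wo.t();
    mat dQ(d.B * d.T2, d.dqk, arma::fill::zeros);
    mat dK(d.B * d.T2, d.dqk, arma::fill::zeros);
    mat dV(d.B * d.T2, d.dv, arma::fill::zeros);
    mat drel(d.H, 2 * d.T2 - 1, arma::fill::zeros);
    std::vector<mat> dSsum(d.H, mat(d.T2, d.T2, arma::fill::zeros));
    for (int b = 0; b < d.B; ++b) {
      int r0 = b * d.T2, r1 = (b + 1) * d.T2 - 1;
      for (int h = 0; h < d.H; ++h) {
        int q0 = h * d.dkh, q1 = (h + 1) * d.dkh - 1;
        int v0 = h * d.dvh, v1 = (h + 1) * d.dvh - 1;
        const mat& A = lc.A.slice(b * d.H + h);
        mat dOh = dO.submat(r0, v0, r1, v1);
        mat dA = dOh * lc.V.submat(r0, v0, r1, v1).t();
        dV.submat(r0, v0, r1, v1) = A.t() * dOh;
        mat dS = A % (dA.each_col() - arma::sum(dA % A, 1));
        dSsum[h] += dS;
        dQ.submat(r0, q0, r1, q1) = dS * lc.K.submat(r0, q0, r1, q1) / sq;
        dK.submat(r0, q0, r1, q1) = dS.t() * lc.Q.submat(r0, q0, r1, q1) / sq;
      }
    }
    for (int h = 0; h < d.H; ++h)
      for (int t = 0; t < d.T2; ++t)
        for (int s = 0; s < d.T2; ++s)
          drel(h, s - t + d.T2 - 1) += dSsum[h](t, s);
    g[enc_name(l, "rel")] = drel;
    g[enc_name(l, "wq")] = lc.Xin.t() * dQ;
    g[enc_name(l, "bq")] = vec((arma::sum(dQ, 0)).t());
    g[enc_name(l, "wk")] = lc.Xin.t() * dK;
    g[enc_name(l, "bk")] = vec((arma::sum(dK, 0)).t());
    g[enc_name(l, "wv")] = lc.Xin.t() * dV;
    g[enc_name(l, "bv")] = vec((arma::sum(dV, 0)).t());
    dX = dR1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  }

  mat dMl(d.B * d.Tm, d.D), dMr(d.B * d.Tm, d.D);
  for (int b = 0; b < d.B; ++b) {
    dMl.rows(b * d.Tm, (b + 1) * d.Tm - 1) =
      dX.rows(b * d.T2, b * d.T2 + d.Tm - 1);
    dMr.rows(b * d.Tm, (b + 1) * d.Tm - 1) =
      dX.rows(b * d.T2 + d.Tm, (b + 1) * d.T2 - 1);
  }
  ConvGrads gl = conv_bwd(d, cl, dMl, Wc, Wm, want_input_grad);
  ConvGrads gr = d.tie_conv ? conv_bwd(d, cr, dMr, Wc, Wm, want_input_grad)
                            : conv_bwd(d, cr, dMr, Wc_r, Wm, want_input_grad);
  g["mlp_w"] = gl.dWm + gr.dWm;
  g["mlp_b"] = vec((gl.dbm + gr.dbm).t());
  if (d.tie_conv) {
    g["conv_w"] = gl.dWc + gr.dWc;
    g["conv_b"] = vec((gl.dbc + gr.dbc).t());
  } else {
    g["conv_w"] = gl.dWc;
    g["conv_b"] = vec(gl.dbc.t());
    g["conv_w_r"] = gr.dWc;
    g["conv_b_r"] = vec(gr.dbc.t());
  }
  if (want_grads) out["grads"] = g;
  if (want_input_grad) {
    out["dX_l"] = gl.dX;
    out["dX_r"] = gr.dX;
  }
  return out;
}
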