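// Forward/backward engine for the three-stream 2D convolutional regression
// network: 3x3 same-padded convolutions, batch normalization, ReLU, 2x2
// max pooling (ceil), global mean pooling, dense head, inverted dropout and
// MSE loss.
//
// Feature maps are stored planar (channels-last): an (H*W*B x C) matrix
// whose columns are whole channel planes with the spatial index fastest.
// Convolutions either run as one GEMM against an (H*W*B x 9*Cin) im2col
// matrix (wide layers) or as a direct stencil of contiguous axpy/dot
// runs (narrow layers, where building im2col would dominate). Column
// k*Cin + ci of the im2col matrix is the input channel ci shifted by
// kernel tap k = (dy, dx) = (k % 3 - 1, k / 3 - 1), zero outside.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct Dims { int H, W, B; };

// iterate the valid contiguous runs of a spatial shift (dy, dx):
// fn(dst_offset, src_offset, run_length)
template <class F>
inline void shift_runs(const Dims& d, int dy, int dx, F fn) {
  const int H = d.H, W = d.W, B = d.B;
  const int i0 = std::max(0, -dy), i1 = H - 1 - std::max(0, dy);
  if (i0 > i1) return;
  const int len = i1 - i0 + 1;
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < W; ++j) {
      const int js = j + dx;
      if (js < 0 || js >= W) continue;
      fn(i0 + H * (j + (long)W * b), i0 + dy + H * (js + (long)W * b), len);
    }
}

void im2col(const mat& F, const Dims& d, mat& out) {
  const int Cin = F.n_cols;
  out.zeros(F.n_rows, (uword)9 * Cin);
  for (int k = 0; k < 9; ++k) {
    const int dy = k % 3 - 1, dx = k / 3 - 1;
    for (int c = 0; c < Cin; ++c) {
      const double* s = F.colptr(c);
      double* t = out.colptr((uword)(k * Cin + c));
      shift_runs(d, dy, dx, [&](long dst, long src, int len) {
        std::memcpy(t + dst, s + src, sizeof(double) * len);
      });
    }
  }
}

// dF(:, c) at p+off_k += G(:, k*Cin + c) at p
void col2im_add(const mat& G, const Dims& d, mat& dF) {
  const int Cin = dF.n_cols;
  for (int k = 0; k < 9; ++k) {
    const int dy = k % 3 - 1, dx = k / 3 - 1;
    for (int c = 0; c < Cin; ++c) {
      const double* s = G.colptr((uword)(k * Cin + c));
      double* t = dF.colptr(c);
      shift_runs(d, dy, dx, [&](long dst, long src, int len) {
        for (int r = 0; r < len; ++r) t[src + r] += s[dst + r];
      });
    }
  }
}

// direct stencil convolution; Y must be zero-initialized
void conv_direct_fwd(const mat& F, const mat& Wm, const Dims& d, mat& Y) {
  const int Cin = F.n_cols, Cout = Y.n_cols;
  for (int k = 0; k < 9; ++k) {
    const int dy = k % 3 - 1, dx = k / 3 - 1;
    for (int co = 0; co < Cout; ++co) {
      double* t = Y.colptr(co);
      for (int ci = 0; ci < Cin; ++ci) {
        const double w = Wm((uword)co, (uword)(k * Cin + ci));
        const double* s = F.colptr(ci);
        shift_runs(d, dy, dx, [&](long dst, long src, int len) {
          for (int r = 0; r < len; ++r) t[dst + r] += w * s[src + r];
        });
      }
    }
  }
}

// dW and dF for the direct path; dF may be null (first layer)
void conv_direct_bwd(const mat& F, const mat& Wm, const mat& dY, const Dims& d,
                     mat& dW, mat* dF) {
  const int Cin = F.n_cols, Cout = dY.n_cols;
  dW.zeros(Wm.n_rows, Wm.n_cols);
  for (int k = 0; k < 9; ++k) {
    const int dy = k % 3 - 1, dx = k / 3 - 1;
    for (int co = 0; co < Cout; ++co) {
      const double* g = dY.colptr(co);
      for (int ci = 0; ci < Cin; ++ci) {
        const double w = Wm((uword)co, (uword)(k * Cin + ci));
        const double* s = F.colptr(ci);
        double* df = dF ? dF->colptr(ci) : nullptr;
        double acc = 0.0;
        shift_runs(d, dy, dx, [&](long dst, long src, int len) {
          for (int r = 0; r < len; ++r) acc += g[dst + r] * s[src + r];
          if (df)
            for (int r = 0; r < len; ++r) df[src + r] += w * g[dst + r];
        });
        dW((uword)co, (uword)(k * Cin + ci)) += acc;
      }
    }
  }
}

// im2col pays off once the GEMM is fat enough; below this the stencil wins
inline bool use_direct(int cin, int cout) { return cin * cout <= 256; }

struct PoolCache { arma::umat idx; Dims din, dout; };

mat maxpool_forward(const mat& F, const Dims& d, PoolCache& pc) {
  const int H2 = (d.H + 1) / 2, W2 = (d.W + 1) / 2;
  const int C = F.n_cols;
  mat Y((uword)H2 * W2 * d.B, (uword)C);
  pc.idx.set_size(Y.n_rows, C);
  pc.din = d; pc.dout = {H2, W2, d.B};
  for (int c = 0; c < C; ++c) {
    const double* s = F.colptr(c);
    double* t = Y.colptr(c);
    uword* ix = pc.idx.colptr(c);
    for (int b = 0; b < d.B; ++b)
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          double best = -arma::datum::inf; long bi = 0;
          for (int jj = 2 * j; jj < std::min(2 * j + 2, d.W); ++jj)
            for (int ii = 2 * i; ii < std::min(2 * i + 2, d.H); ++ii) {
              const long sc = ii + d.H * (jj + (long)d.W * b);
              if (s[sc] > best) { best = s[sc]; bi = sc; }
            }
          const long oc = i + H2 * (j + (long)W2 * b);
          t[oc] = best;
          ix[oc] = (uword)bi;
        }
  }
  return Y;
}

mat maxpool_backward(const mat& dY, const PoolCache& pc) {
  mat dF((uword)pc.din.H * pc.din.W * pc.din.B, dY.n_cols, arma::fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const double* g = dY.colptr(c);
    const uword* ix = pc.idx.colptr(c);
    double* t = dF.colptr(c);
    for (uword p = 0; p < dY.n_rows; ++p) t[ix[p]] += g[p];
  }
  return dF;
}

struct BNCache { mat xhat; vec invstd; };

// Batch norm per channel (column), applied in place; N = rows
// (batch x spatial). Caches xhat only when a backward pass will follow.
void bn_forward(mat& Y, const vec& gamma, const vec& beta,
                double* rmean, double* rvar, bool training, bool want_cache,
                double momentum, double eps, BNCache& cache) {
  const uword C = Y.n_cols, N = Y.n_rows;
  vec mu(C), var(C);
  if (training) {
    for (uword c = 0; c < C; ++c) {
      const double* y = Y.colptr(c);
      double s = 0, s2 = 0;
      for (uword p = 0; p < N; ++p) { s += y[p]; s2 += y[p] * y[p]; }
      mu(c) = s / (double)N;
      var(c) = std::max(s2 / (double)N - mu(c) * mu(c), 0.0);
      rmean[c] = (1 - momentum) * rmean[c] + momentum * mu(c);
      rvar[c] = (1 - momentum) * rvar[c] + momentum * var(c);
    }
  } else {
    for (uword c = 0; c < C; ++c) { mu(c) = rmean[c]; var(c) = rvar[c]; }
  }
  cache.invstd = 1.0 / arma::sqrt(var + eps);
  if (want_cache) cache.xhat.set_size(N, C);
  for (uword c = 0; c < C; ++c) {
    const double a = gamma(c) * cache.invstd(c);
    const double b = beta(c) - mu(c) * a;
    double* y = Y.colptr(c);
    if (want_cache) {
      const double im = cache.invstd(c), m = mu(c);
      double* xh = cache.xhat.colptr(c);
      for (uword p = 0; p < N; ++p) {
        xh[p] = (y[p] - m) * im;
        y[p] = a * y[p] + b;
      }
    } else {
      for (uword p = 0; p < N; ++p) y[p] = a * y[p] + b;
    }
  }
}

mat bn_backward(const mat& dY, const vec& gamma, const BNCache& cache,
                vec& dgamma, vec& dbeta) {
  const uword C = dY.n_cols, N = dY.n_rows;
  dgamma.set_size(C); dbeta.set_size(C);
  mat dF(N, C);
  for (uword c = 0; c < C; ++c) {
    const double* g = dY.colptr(c);
    const double* xh = cache.xhat.colptr(c);
    double sg = 0, sgx = 0;
    for (uword p = 0; p < N; ++p) { sg += g[p]; sgx += g[p] * xh[p]; }
    dgamma(c) = sgx;
    dbeta(c) = sg;
    const double ga = gamma(c), im = cache.invstd(c);
    const double m1 = sg / (double)N, m2 = sgx / (double)N;
    double* t = dF.colptr(c);
    for (uword p = 0; p < N; ++p)
      t[p] = ga * im * (g[p] - m1 - xh[p] * m2);
  }
  return dF;
}

void dropout_inplace(mat& Y, mat& mask, double rate, std::mt19937_64& rng) {
  mask.set_size(Y.n_rows, Y.n_cols);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const double keep = 1.0 - rate;
  double* m = mask.memptr();
  double* y = Y.memptr();
  for (uword t = 0; t < Y.n_elem; ++t) {
    m[t] = U(rng) < keep ? 1.0 / keep : 0.0;
    y[t] *= m[t];
  }
}

mat theta_mat(const NumericVector& theta, int off, int r, int c) {
  return mat(const_cast<double*>(REAL(theta) + off), r, c, false, true);
}

vec theta_vec(const NumericVector& theta, int off, int n) {
  return vec(const_cast<double*>(REAL(theta) + off), n, false, true);
}

inline void relu_inplace(mat& Y) {
  double* y = Y.memptr();
  for (uword t = 0; t < Y.n_elem; ++t) if (y[t] < 0) y[t] = 0;
}

inline void relu_mask_inplace(mat& dY, const mat& preact) {
  const double* p = preact.memptr();
  double* g = dY.memptr();
  for (uword t = 0; t < dY.n_elem; ++t) if (p[t] <= 0) g[t] = 0;
}

struct StackCache {
  std::vector<mat> cols;       // cached im2col (gemm path layers)
  std::vector<mat> fin;        // cached input (direct path layers)
  std::vector<char> direct;    // which path layer l used
  std::vector<Dims> dims;      // dims of that layer's input
  std::vector<mat> preact;     // post-BN (or post-bias) pre-activation
  std::vector<BNCache> bn;
  std::vector<PoolCache> pool;
  std::vector<mat> dropmask;
  Dims lastdims;
};

} // namespace

// [[Rcpp::export(name = ".cnn_run")]]
List cnn_run(NumericVector theta, NumericVector state, List plan, List xlist,
             NumericVector y, bool training, bool want_grad, int dropout_seed) {
  List stacks = plan["stacks"];
  List head = plan["head"];
  const double momentum = as<double>(plan["bn_momentum"]);
  const double eps = as<double>(plan["bn_eps"]);
  const double drop_conv = as<double>(plan["drop_rate_conv"]);
  const double drop_dense = as<double>(plan["drop_rate_dense"]);
  const int n_planes = stacks.size();
  NumericVector state_new = clone(state);
  vec grad;
  if (want_grad) grad.zeros(theta.size());
  std::mt19937_64 rng((uint64_t)dropout_seed * 2654435761ULL + 1ULL);

  // ---- per-plane stack forward ----
  int B = -1;
  std::vector<StackCache> caches(n_planes);
  std::vector<mat> feats(n_planes); // (B, C) after global mean pool
  for (int p = 0; p < n_planes; ++p) {
    List sp = stacks[p];
    NumericVector xarr = xlist[p];
    IntegerVector xd = xarr.attr("dim"); // H, W, C, B
    const int H = xd[0], Wd = xd[1], Cin = xd[2], Bp = xd[3];
    if (B < 0) B = Bp;
    if (Bp != B) stop("inconsistent batch sizes across planes");
    Dims d{H, Wd, B};
    const long HW = (long)H * Wd;
    mat F((uword)(HW * B), (uword)Cin);
    {
      const double* xp = REAL(xarr);
      for (int c = 0; c < Cin; ++c) {
        double* t = F.colptr(c);
        for (int b = 0; b < B; ++b)
          std::memcpy(t + HW * b, xp + HW * (c + (long)Cin * b),
                      sizeof(double) * HW);
      }
    }
    IntegerVector filters = sp["filters"], w_off = sp["w_off"], b_off = sp["b_off"],
      g_off = sp["g_off"], be_off = sp["be_off"], st_off = sp["st_off"];
    LogicalVector bn = sp["bn"], pool = sp["pool"], drop = sp["drop"];
    const int L = filters.size();
    StackCache& sc = caches[p];
    sc.cols.resize(L); sc.fin.resize(L); sc.direct.assign(L, 0);
    sc.dims.resize(L); sc.preact.resize(L);
    sc.bn.resize(L); sc.pool.resize(L); sc.dropmask.resize(L);
    for (int l = 0; l < L; ++l) {
      const int cin = F.n_cols, cout = filters[l];
      sc.dims[l] = d;
      mat Wm = theta_mat(theta, w_off[l], cout, 9 * cin);
      mat Y;
      if (use_direct(cin, cout)) {
        sc.direct[l] = 1;
        Y.zeros(F.n_rows, (uword)cout);
        conv_direct_fwd(F, Wm, d, Y);
        if (want_grad) sc.fin[l] = std::move(F);
      } else {
        im2col(F, d, sc.cols[l]);
        Y = sc.cols[l] * Wm.t();
        if (!want_grad) sc.cols[l].reset();
      }
      if (bn[l]) {
        vec gamma = theta_vec(theta, g_off[l], cout);
        vec beta = theta_vec(theta, be_off[l], cout);
        bn_forward(Y, gamma, beta, REAL(state_new) + st_off[l],
                   REAL(state_new) + st_off[l] + cout, training, want_grad,
                   momentum, eps, sc.bn[l]);
      } else {
        vec bias = theta_vec(theta, b_off[l], cout);
        Y.each_row() += bias.t();
      }
      if (want_grad) sc.preact[l] = Y;
      relu_inplace(Y);
      if (drop[l] && training && drop_conv > 0)
        dropout_inplace(Y, sc.dropmask[l], drop_conv, rng);
      if (pool[l]) {
        Y = maxpool_forward(Y, d, sc.pool[l]);
        d = sc.pool[l].dout;
      }
      F = std::move(Y);
    }
    sc.lastdims = d;
    // global mean pool over spatial positions
    const long S = (long)d.H * d.W;
    mat feat((uword)B, F.n_cols);
    for (uword c = 0; c < F.n_cols; ++c) {
      const double* s = F.colptr(c);
      for (int b = 0; b < B; ++b) {
        double acc = 0;
        for (long r = 0; r < S; ++r) acc += s[S * b + r];
        feat((uword)b, c) = acc / (double)S;
      }
    }
    feats[p] = std::move(feat);
  }

  // ---- head forward ----
  uword concat_cols = 0;
  for (int p = 0; p < n_planes; ++p) concat_cols += feats[p].n_cols;
  mat Fh((uword)B, concat_cols);
  {
    uword c0 = 0;
    for (int p = 0; p < n_planes; ++p) {
      Fh.cols(c0, c0 + feats[p].n_cols - 1) = feats[p];
      c0 += feats[p].n_cols;
    }
  }
  IntegerVector hsz = head["sizes"], hw_off = head["w_off"], hb_off = head["b_off"],
    hg_off = head["g_off"], hbe_off = head["be_off"], hst_off = head["st_off"];
  LogicalVector hbn = head["bn"], hbias = head["bias"], hdrop = head["drop"],
    hrelu = head["relu"];
  const int HL = hsz.size();
  std::vector<mat> hin(HL), hpre(HL), hmask(HL);
  std::vector<BNCache> hbnc(HL);
  for (int l = 0; l < HL; ++l) {
    const int cout = hsz[l];
    hin[l] = Fh;
    mat Wm = theta_mat(theta, hw_off[l], cout, Fh.n_cols);
    mat Y = Fh * Wm.t();
    if (hbn[l]) {
      vec gamma = theta_vec(theta, hg_off[l], cout);
      vec beta = theta_vec(theta, hbe_off[l], cout);
      bn_forward(Y, gamma, beta, REAL(state_new) + hst_off[l],
                 REAL(state_new) + hst_off[l] + cout, training, true,
                 momentum, eps, hbnc[l]);
    } else if (hbias[l]) {
      vec bias = theta_vec(theta, hb_off[l], cout);
      Y.each_row() += bias.t();
    }
    hpre[l] = Y;
    if (hrelu[l]) relu_inplace(Y);
    if (hdrop[l] && training && drop_dense > 0)
      dropout_inplace(Y, hmask[l], drop_dense, rng);
    Fh = std::move(Y);
  }
  vec preds = Fh.col(0);

  double loss = NA_REAL;
  if (y.size() > 0) {
    vec yy(REAL(y), y.size());
    loss = arma::mean(arma::square(preds - yy));
  }

  List out = List::create(_["preds"] = NumericVector(preds.begin(), preds.end()),
                          _["loss"] = loss, _["state"] = state_new);
  if (!want_grad) return out;
  if (y.size() == 0) stop("gradient requested without targets");

  // ---- backward ----
  vec yy(REAL(y), y.size());
  mat dY((uword)B, 1);
  dY.col(0) = 2.0 * (preds - yy) / (double)B;
  for (int l = HL - 1; l >= 0; --l) {
    const int cout = hsz[l];
    if (hdrop[l] && training && drop_dense > 0) dY %= hmask[l];
    if (hrelu[l]) relu_mask_inplace(dY, hpre[l]);
    if (hbn[l]) {
      vec gamma = theta_vec(theta, hg_off[l], cout);
      vec dgamma, dbeta;
      dY = bn_backward(dY, gamma, hbnc[l], dgamma, dbeta);
      grad.subvec(hg_off[l], hg_off[l] + cout - 1) += dgamma;
      grad.subvec(hbe_off[l], hbe_off[l] + cout - 1) += dbeta;
    } else if (hbias[l]) {
      grad.subvec(hb_off[l], hb_off[l] + cout - 1) += arma::sum(dY, 0).t();
    }
    mat Wm = theta_mat(theta, hw_off[l], cout, hin[l].n_cols);
    mat dW = dY.t() * hin[l];
    vec dWv(dW.memptr(), dW.n_elem, false, true);
    grad.subvec(hw_off[l], hw_off[l] + dW.n_elem - 1) += dWv;
    dY = dY * Wm;
  }
  // split concat gradient back to stacks
  uword c0 = 0;
  for (int p = 0; p < n_planes; ++p) {
    List sp = stacks[p];
    StackCache& sc = caches[p];
    const uword C = feats[p].n_cols;
    mat dfeat = dY.cols(c0, c0 + C - 1); // (B, C)
    c0 += C;
    // undo global mean pool
    const Dims dl = sc.lastdims;
    const long S = (long)dl.H * dl.W;
    mat dF((uword)(S * B), C);
    for (uword c = 0; c < C; ++c) {
      double* t = dF.colptr(c);
      for (int b = 0; b < B; ++b) {
        const double v = dfeat((uword)b, c) / (double)S;
        for (long r = 0; r < S; ++r) t[S * b + r] = v;
      }
    }
    IntegerVector filters = sp["filters"], w_off = sp["w_off"], b_off = sp["b_off"],
      g_off = sp["g_off"], be_off = sp["be_off"];
    LogicalVector bn = sp["bn"], pool = sp["pool"], drop = sp["drop"];
    for (int l = filters.size() - 1; l >= 0; --l) {
      const int cout = filters[l];
      if (pool[l]) dF = maxpool_backward(dF, sc.pool[l]);
      if (drop[l] && training && drop_conv > 0) dF %= sc.dropmask[l];
      relu_mask_inplace(dF, sc.preact[l]);
      if (bn[l]) {
        vec gamma = theta_vec(theta, g_off[l], cout);
        vec dgamma, dbeta;
        dF = bn_backward(dF, gamma, sc.bn[l], dgamma, dbeta);
        grad.subvec(g_off[l], g_off[l] + cout - 1) += dgamma;
        grad.subvec(be_off[l], be_off[l] + cout - 1) += dbeta;
      } else {
        grad.subvec(b_off[l], b_off[l] + cout - 1) += arma::sum(dF, 0).t();
      }
      if (sc.direct[l]) {
        const int cin = sc.fin[l].n_cols;
        mat Wm = theta_mat(theta, w_off[l], cout, 9 * cin);
        mat dW, dFin;
        if (l > 0) dFin.zeros(dF.n_rows, (uword)cin);
        conv_direct_bwd(sc.fin[l], Wm, dF, sc.dims[l], dW,
                        l > 0 ? &dFin : nullptr);
        vec dWv(dW.memptr(), dW.n_elem, false, true);
        grad.subvec(w_off[l], w_off[l] + dW.n_elem - 1) += dWv;
        if (l > 0) dF = std::move(dFin);
      } else {
        const int cin9 = sc.cols[l].n_cols;
        mat Wm = theta_mat(theta, w_off[l], cout, cin9);
        mat dW = dF.t() * sc.cols[l];
        vec dWv(dW.memptr(), dW.n_elem, false, true);
        grad.subvec(w_off[l], w_off[l] + dW.n_elem - 1) += dWv;
        if (l > 0) {
          mat G = dF * Wm;            // gradient w.r.t. im2col columns
          mat dFin(dF.n_rows, (uword)(cin9 / 9), arma::fill::zeros);
          col2im_add(G, sc.dims[l], dFin);
          dF = std::move(dFin);
        }
      }
    }
  }
  out["grad"] = NumericVector(grad.begin(), grad.end());
  return out;
}
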