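// Convolution kernels for the autodiff engine: im2col / col2im plus the
// forward and backward gemms, working directly on R's column-major (H, W, C)
// arrays through BLAS. These are the only hot loops of the package; all
// orchestration stays in R.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// gather patches: xp is the padded (Hp, Wp, C) buffer; output is the
// (Ho*Wo) x (k*k*C) patch matrix with taps ordered ky-fastest, then kx,
// then channel.
static void im2col_core(const double* xp, int Hp, int Wp, int C, int k,
                        int stride, int Ho, int Wo, double* out) {
  const R_xlen_t n = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* sl = xp + (R_xlen_t)c * Hp * Wp;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        double* dst = out + ((R_xlen_t)(ky + kx * k + c * k * k)) * n;
        for (int wo = 0; wo < Wo; ++wo) {
          const double* src = sl + (R_xlen_t)(wo * stride + kx) * Hp + ky;
          double* d = dst + (R_xlen_t)wo * Ho;
          if (stride == 1) {
            std::memcpy(d, src, sizeof(double) * Ho);
          } else {
            for (int ho = 0; ho < Ho; ++ho) d[ho] = src[ho * stride];
          }
        }
      }
    }
  }
}

// scatter-add the patch-matrix gradient back into the padded input buffer
static void col2im_core(const double* dcol, int Hp, int Wp, int C, int k,
                        int stride, int Ho, int Wo, double* dxp) {
  const R_xlen_t n = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* sl = dxp + (R_xlen_t)c * Hp * Wp;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const double* src = dcol + ((R_xlen_t)(ky + kx * k + c * k * k)) * n;
        for (int wo = 0; wo < Wo; ++wo) {
          double* d = sl + (R_xlen_t)(wo * stride + kx) * Hp + ky;
          const double* s = src + (R_xlen_t)wo * Ho;
          if (stride == 1) {
            for (int ho = 0; ho < Ho; ++ho) d[ho] += s[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) d[ho * stride] += s[ho];
          }
        }
      }
    }
  }
}

static void pad_into(const double* x, int H, int W, int C, int pad,
                     std::vector<double>& xp, int Hp, int Wp) {
  std::fill(xp.begin(), xp.end(), 0.0);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      std::memcpy(xp.data() + ((R_xlen_t)c * Wp + w + pad) * Hp + pad,
                  x + ((R_xlen_t)c * W + w) * H, sizeof(double) * H);
}

static void dgemm_(char ta, char tb, int m, int n, int kk, double alpha,
                   const double* a, int lda, const double* b, int ldb,
                   double beta, double* c, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, a, &lda, b, &ldb, &beta,
                  c, &ldc FCONE FCONE);
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
List conv_fwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector b,
                  int H, int W, int C, int k, int stride, int pad) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  const int cout = Wm.ncol();
  const R_xlen_t n = (R_xlen_t)Ho * Wo;
  NumericMatrix xcol((int)n, k * k * C);
  if (pad == 0) {
    im2col_core(REAL(x), Hp, Wp, C, k, stride, Ho, Wo, REAL(xcol));
  } else {
    std::vector<double> xp((R_xlen_t)Hp * Wp * C);
    pad_into(REAL(x), H, W, C, pad, xp, Hp, Wp);
    im2col_core(xp.data(), Hp, Wp, C, k, stride, Ho, Wo, REAL(xcol));
  }
  NumericVector y((R_xlen_t)n * cout);
  dgemm_('N', 'N', (int)n, cout, k * k * C, 1.0, REAL(xcol), (int)n,
         REAL(Wm), k * k * C, 0.0, REAL(y), (int)n);
  double* yp = REAL(y);
  for (int co = 0; co < cout; ++co) {
    const double bc = b[co];
    double* col = yp + (R_xlen_t)co * n;
    for (R_xlen_t i = 0; i < n; ++i) col[i] += bc;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout);
  return List::create(_["y"] = y, _["xcol"] = xcol);
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector dy, NumericMatrix xcol, NumericMatrix Wm,
                  int H, int W, int C, int k, int stride, int pad,
                  bool need_dx) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  const int cout = Wm.ncol(), kkc = k * k * C;
  const R_xlen_t n = (R_xlen_t)Ho * Wo;
  NumericMatrix dW(kkc, cout);
  dgemm_('T', 'N', kkc, cout, (int)n, 1.0, REAL(xcol), (int)n, REAL(dy),
         (int)n, 0.0, REAL(dW), kkc);
  NumericVector db(cout);
  const double* dyp = REAL(dy);
  for (int co = 0; co < cout; ++co) {
    double s = 0.0;
    const double* col = dyp + (R_xlen_t)co * n;
    for (R_xlen_t i = 0; i < n; ++i) s += col[i];
    db[co] = s;
  }
  if (!need_dx)
    return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = R_NilValue);
  std::vector<double> dcol((R_xlen_t)n * kkc);
  dgemm_('N', 'T', (int)n, kkc, cout, 1.0, dyp, (int)n, REAL(Wm), kkc, 0.0,
         dcol.data(), (int)n);
  NumericVector dx((R_xlen_t)H * W * C);
  if (pad == 0) {
    col2im_core(dcol.data(), Hp, Wp, C, k, stride, Ho, Wo, REAL(dx));
  } else {
    std::vector<double> dxp((R_xlen_t)Hp * Wp * C, 0.0);
    col2im_core(dcol.data(), Hp, Wp, C, k, stride, Ho, Wo, dxp.data());
    double* out = REAL(dx);
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w)
        std::memcpy(out + ((R_xlen_t)c * W + w) * H,
                    dxp.data() + ((R_xlen_t)c * Wp + w + pad) * Hp + pad,
                    sizeof(double) * H);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Per-channel spatial normalization, forward (training statistics):
// returns y, the per-channel mean and the inverse standard deviation.
// [[Rcpp::export(name = ".norm_fwd_cpp")]]
List norm_fwd_cpp(NumericVector x, NumericVector g, NumericVector b,
                  int HW, int C, double eps) {
  NumericVector y((R_xlen_t)HW * C), mu(C), inv(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double* col = xp + (R_xlen_t)c * HW;
    double s = 0.0;
    for (int i = 0; i < HW; ++i) s += col[i];
    const double m = s / HW;
    double v = 0.0;
    for (int i = 0; i < HW; ++i) { const double d = col[i] - m; v += d * d; }
    v /= HW;
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m; inv[c] = is;
    const double a = g[c] * is, bb = b[c] - a * m;
    double* yc = yp + (R_xlen_t)c * HW;
    for (int i = 0; i < HW; ++i) yc[i] = a * col[i] + bb;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv);
}

// Backward of the spatial normalization (training-statistics branch).
// [[Rcpp::export(name = ".norm_bwd_cpp")]]
List norm_bwd_cpp(NumericVector dy, NumericVector x, NumericVector mu,
                  NumericVector inv, NumericVector g, int HW, int C,
                  bool need_dx) {
  NumericVector dg(C), db(C);
  NumericVector dx(need_dx ? (R_xlen_t)HW * C : 0);
  const double* dyp = REAL(dy);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dyp + (R_xlen_t)c * HW;
    const double* xc = xp + (R_xlen_t)c * HW;
    const double m = mu[c], is = inv[c];
    double s1 = 0.0, s2 = 0.0, sg = 0.0;
    for (int i = 0; i < HW; ++i) {
      const double xh = (xc[i] - m) * is;
      s1 += dyc[i];
      s2 += dyc[i] * xh;
      sg += dyc[i] * xh;
    }
    dg[c] = sg; db[c] = s1;
    if (need_dx) {
      const double m1 = s1 / HW, m2 = s2 / HW, a = g[c] * is;
      double* dxc = REAL(dx) + (R_xlen_t)c * HW;
      for (int i = 0; i < HW; ++i) {
        const double xh = (xc[i] - m) * is;
        dxc[i] = a * (dyc[i] - m1 - xh * m2);
      }
    }
  }
  if (need_dx)
    return List::create(_["dg"] = dg, _["db"] = db, _["dx"] = dx);
  return List::create(_["dg"] = dg, _["db"] = db, _["dx"] = R_NilValue);
}
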