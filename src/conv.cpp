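#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>
using namespace Rcpp;

// 3x3 convolution on tensors stored as ((H*W*B) x C) column-major matrices,
// rows ordered height-fastest, then width, then batch ("same" padding;
// stride 1 or 2, Keras-style begin/end padding). The per-image im2col
// buffer is small, and the multiply is a BLAS dgemm, so peak memory stays
// modest regardless of batch size.

static inline void pad_sizes(int H, int s, int &beg, int &end) {
  int tot = (H % s == 0) ? (3 - s > 0 ? 3 - s : 0) : (3 - H % s > 0 ? 3 - H % s : 0);
  beg = tot / 2; end = tot - beg;
}

struct ConvDims {
  int H, W, B, C, s, ph, pw, Hp, Wp, Ho, Wo;
};

static ConvDims conv_dims(int H, int W, int B, int C, int s) {
  ConvDims d; d.H = H; d.W = W; d.B = B; d.C = C; d.s = s;
  int pe, we;
  pad_sizes(H, s, d.ph, pe); pad_sizes(W, s, d.pw, we);
  d.Hp = H + d.ph + pe; d.Wp = W + d.pw + we;
  d.Ho = (H + s - 1) / s; d.Wo = (W + s - 1) / s;
  return d;
}

// copy image b, all channels, into the zeroed padded plane buffer
static void fill_padded(const double *xm, int nrowX, const ConvDims &d,
                        int b, std::vector<double> &xp) {
  std::fill(xp.begin(), xp.end(), 0.0);
  const int planeP = d.Hp * d.Wp;
  for (int c = 0; c < d.C; ++c) {
    const double *src = xm + (size_t)c * nrowX + (size_t)b * d.H * d.W;
    double *dst = xp.data() + (size_t)c * planeP;
    for (int w = 0; w < d.W; ++w)
      std::memcpy(dst + (size_t)(w + d.pw) * d.Hp + d.ph,
                  src + (size_t)w * d.H, d.H * sizeof(double));
  }
}

// im2col: buf is (Ho*Wo) x (9*C), column (o + 9*c) holds offset o of chan c
static void im2col(const std::vector<double> &xp, const ConvDims &d,
                   std::vector<double> &buf) {
  const int n_out = d.Ho * d.Wo, planeP = d.Hp * d.Wp;
  for (int c = 0; c < d.C; ++c) {
    const double *pl = xp.data() + (size_t)c * planeP;
    for (int o = 0; o < 9; ++o) {
      const int dr = o % 3, dc = o / 3;
      double *col = buf.data() + (size_t)(o + 9 * c) * n_out;
      for (int wo = 0; wo < d.Wo; ++wo) {
        const double *s0 = pl + (size_t)(wo * d.s + dc) * d.Hp + dr;
        double *t0 = col + (size_t)wo * d.Ho;
        if (d.s == 1) std::memcpy(t0, s0, d.Ho * sizeof(double));
        else for (int ho = 0; ho < d.Ho; ++ho) t0[ho] = s0[ho * d.s];
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3x3_fwd(const NumericMatrix &xm, int H, int W, int B,
                              const NumericMatrix &W9, const NumericVector &bias,
                              int stride) {
  const int C = xm.ncol(), cout = W9.ncol();
  ConvDims d = conv_dims(H, W, B, C, stride);
  const int n_out = d.Ho * d.Wo;
  NumericMatrix Y((size_t)n_out * B, cout);
  std::vector<double> xp((size_t)d.Hp * d.Wp * C), buf((size_t)n_out * 9 * C);
  const double one = 1.0, zero = 0.0;
  const int K = 9 * C;
  std::vector<double> yb((size_t)n_out * cout);
  for (int b = 0; b < B; ++b) {
    fill_padded(xm.begin(), xm.nrow(), d, b, xp);
    im2col(xp, d, buf);
    F77_CALL(dgemm)("N", "N", &n_out, &cout, &K, &one, buf.data(), &n_out,
                    W9.begin(), &K, &zero, yb.data(), &n_out FCONE FCONE);
    for (int c = 0; c < cout; ++c) {
      double *dst = Y.begin() + (size_t)c * Y.nrow() + (size_t)b * n_out;
      const double *src = yb.data() + (size_t)c * n_out;
      const double bc = bias[c];
      for (int i = 0; i < n_out; ++i) dst[i] = src[i] + bc;
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3x3_bwd(const NumericMatrix &xm, const NumericMatrix &dY,
                     int H, int W, int B, const NumericMatrix &W9, int stride) {
  const int C = xm.ncol(), cout = W9.ncol();
  ConvDims d = conv_dims(H, W, B, C, stride);
  const int n_out = d.Ho * d.Wo, K = 9 * C, planeP = d.Hp * d.Wp;
  NumericMatrix dX(xm.nrow(), C);
  NumericMatrix dW(K, cout);
  std::vector<double> xp((size_t)planeP * C), buf((size_t)n_out * 9 * C);
  std::vector<double> dyb((size_t)n_out * cout), dbuf((size_t)n_out * K);
  std::vector<double> dxp((size_t)planeP * C);
  const double one = 1.0, zero = 0.0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < cout; ++c)
      std::memcpy(dyb.data() + (size_t)c * n_out,
                  dY.begin() + (size_t)c * dY.nrow() + (size_t)b * n_out,
                  n_out * sizeof(double));
    fill_padded(xm.begin(), xm.nrow(), d, b, xp);
    im2col(xp, d, buf);
    // dW += buf^T %*% dyb
    F77_CALL(dgemm)("T", "N", &K, &cout, &n_out, &one, buf.data(), &n_out,
                    dyb.data(), &n_out, &one, dW.begin(), &K FCONE FCONE);
    // dbuf = dyb %*% W9^T
    F77_CALL(dgemm)("N", "T", &n_out, &K, &cout, &one, dyb.data(), &n_out,
                    W9.begin(), &K, &zero, dbuf.data(), &n_out FCONE FCONE);
    // col2im accumulate into the padded plane, then crop into dX
    std::fill(dxp.begin(), dxp.end(), 0.0);
    for (int c = 0; c < C; ++c) {
      double *pl = dxp.data() + (size_t)c * planeP;
      for (int o = 0; o < 9; ++o) {
        const int dr = o % 3, dc = o / 3;
        const double *col = dbuf.data() + (size_t)(o + 9 * c) * n_out;
        for (int wo = 0; wo < d.Wo; ++wo) {
          double *t0 = pl + (size_t)(wo * d.s + dc) * d.Hp + dr;
          const double *s0 = col + (size_t)wo * d.Ho;
          if (d.s == 1) for (int ho = 0; ho < d.Ho; ++ho) t0[ho] += s0[ho];
          else for (int ho = 0; ho < d.Ho; ++ho) t0[ho * d.s] += s0[ho];
        }
      }
    }
    for (int c = 0; c < C; ++c) {
      const double *pl = dxp.data() + (size_t)c * planeP;
      double *dst = dX.begin() + (size_t)c * dX.nrow() + (size_t)b * d.H * d.W;
      for (int w = 0; w < d.W; ++w) {
        const double *s0 = pl + (size_t)(w + d.pw) * d.Hp + d.ph;
        for (int h = 0; h < d.H; ++h) dst[(size_t)w * d.H + h] += s0[h];
      }
    }
  }
  return List::create(_["dx"] = dX, _["dW"] = dW);
}

// fused batch-norm helpers: one pass over the data instead of several
// temporary-allocating R vector operations.

// [[Rcpp::export]]
List cpp_bn_fwd(const NumericMatrix &xm, const NumericVector &gamma,
                const NumericVector &beta, double eps) {
  const int n = xm.nrow(), C = xm.ncol();
  NumericMatrix xhat(n, C), y(n, C);
  NumericVector mu(C), var(C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double *x = xm.begin() + (size_t)c * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i];
    const double m = s / n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) { const double d = x[i] - m; v += d * d; }
    v /= n;
    const double is = 1.0 / std::sqrt(v + eps);
    double *xh = xhat.begin() + (size_t)c * n;
    double *yy = y.begin() + (size_t)c * n;
    const double g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      const double h = (x[i] - m) * is;
      xh[i] = h;
      yy[i] = g * h + b;
    }
    mu[c] = m; var[c] = v; istd[c] = is;
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix &dy, const NumericMatrix &xhat,
                const NumericVector &gamma, const NumericVector &istd,
                bool training) {
  const int n = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *d = dy.begin() + (size_t)c * n;
    const double *xh = xhat.begin() + (size_t)c * n;
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) { sg += d[i] * xh[i]; sb += d[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double sc = gamma[c] * istd[c];
    double *o = dx.begin() + (size_t)c * n;
    if (training) {
      const double a = sb / n, g = sg / n;
      for (int i = 0; i < n; ++i) o[i] = (d[i] - a - xh[i] * g) * sc;
    } else {
      for (int i = 0; i < n; ++i) o[i] = d[i] * sc;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_fwd(const NumericMatrix &xm, double slope) {
  const size_t n = (size_t)xm.nrow() * xm.ncol();
  NumericMatrix y(xm.nrow(), xm.ncol());
  const double *x = xm.begin(); double *o = y.begin();
  for (size_t i = 0; i < n; ++i) o[i] = x[i] >= 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_bwd(const NumericMatrix &xm, const NumericMatrix &dy,
                            double slope) {
  const size_t n = (size_t)xm.nrow() * xm.ncol();
  NumericMatrix dx(dy.nrow(), dy.ncol());
  const double *x = xm.begin(); const double *d = dy.begin();
  double *o = dx.begin();
  for (size_t i = 0; i < n; ++i) o[i] = x[i] >= 0 ? d[i] : slope * d[i];
  return dx;
}
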