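// Hot inner loops of the convolution layers.
//
// Activations are column-major (H, W, N, C) arrays. im2col builds the
// (H*W*N) x (k*k*C) patch matrix with implicit zero padding of (k-1)/2 on
// each spatial side; col2im is its adjoint (scatter-add), used for the
// input gradient. The surrounding matrix products stay in R/BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  const int HWN = H * W * N;
  const int k2 = k * k;
  NumericMatrix P(HWN, k2 * C);
  const double* xp = x.begin();
  double* Pp = P.begin();
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = xp + (R_xlen_t)ci * HWN;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int o = di + k * dj;
        double* col = Pp + (R_xlen_t)(o + k2 * ci) * HWN;
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + (R_xlen_t)n * H * W;
          double* cn = col + (R_xlen_t)n * H * W;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - p;
            double* cj = cn + (R_xlen_t)j * H;
            if (sj < 0 || sj >= W) {
              for (int i = 0; i < H; ++i) cj[i] = 0.0;
              continue;
            }
            const double* xj = xn + (R_xlen_t)sj * H;
            const int si0 = di - p;
            for (int i = 0; i < H; ++i) {
              const int si = i + si0;
              cj[i] = (si >= 0 && si < H) ? xj[si] : 0.0;
            }
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dP, int H, int W, int N, int C,
                         int k) {
  const int p = (k - 1) / 2;
  const int HWN = H * W * N;
  const int k2 = k * k;
  NumericVector dx((R_xlen_t)HWN * C);
  double* dxp = dx.begin();
  const double* Pp = dP.begin();
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dxp + (R_xlen_t)ci * HWN;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int o = di + k * dj;
        const double* col = Pp + (R_xlen_t)(o + k2 * ci) * HWN;
        for (int n = 0; n < N; ++n) {
          double* xn = xc + (R_xlen_t)n * H * W;
          const double* cn = col + (R_xlen_t)n * H * W;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - p;
            if (sj < 0 || sj >= W) continue;
            double* xj = xn + (R_xlen_t)sj * H;
            const double* cj = cn + (R_xlen_t)j * H;
            const int si0 = di - p;
            for (int i = 0; i < H; ++i) {
              const int si = i + si0;
              if (si >= 0 && si < H) xj[si] += cj[i];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// Batch-norm forward core: given the (n x C) activation matrix, per-channel
// mean/invstd and affine (gamma, beta), writes xhat and the output in one
// pass.
// [[Rcpp::export]]
List bn_apply_cpp(NumericMatrix x, NumericVector mu, NumericVector invstd,
                  NumericVector gamma, NumericVector beta) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix xhat(n, C), y(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
    const double* xc = x.begin() + (R_xlen_t)c * n;
    double* hc = xhat.begin() + (R_xlen_t)c * n;
    double* yc = y.begin() + (R_xlen_t)c * n;
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * is;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// Batch-norm backward core: returns dx plus the per-channel gradient sums
// for gamma and beta.
// [[Rcpp::export]]
List bn_backward_cpp(NumericMatrix dy, NumericMatrix xhat,
                     NumericVector invstd, NumericVector gamma) {
  const int n = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = dy.begin() + (R_xlen_t)c * n;
    const double* hc = xhat.begin() + (R_xlen_t)c * n;
    double* xc = dx.begin() + (R_xlen_t)c * n;
    double s1 = 0.0, s2 = 0.0, sb = 0.0, sg = 0.0;
    const double g = gamma[c];
    for (int i = 0; i < n; ++i) {
      const double dxh = dc[i] * g;
      s1 += dxh;
      s2 += dxh * hc[i];
      sb += dc[i];
      sg += dc[i] * hc[i];
      xc[i] = dxh;           // temporarily holds dxhat
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double m1 = s1 / n, m2 = s2 / n, is = invstd[c];
    for (int i = 0; i < n; ++i) {
      xc[i] = is * (xc[i] - m1 - hc[i] * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
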