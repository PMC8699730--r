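// Convolution and pooling kernels for the CNN engine.
//
// im2col uses a positions-major patch matrix P (Ho*Wo*N rows, k*k*C columns,
// column = one (kh, kw, c) offset), so for stride-1 interior positions each
// (kh, kw, c, pw, n) slice is a contiguous memcpy of Ho doubles in both the
// source image and the destination column. Forward output is P * W with
// weights as (k*k*C) x F; backward reuses the same geometry with
// accumulation. Tensors are column-major H x W x C x N.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvGeom {
  int H, W, C, N, k, stride, pad, Ho, Wo;
  long npos() const { return static_cast<long>(Ho) * Wo; }
};

// gather: P(pos-major) from x; scatter: add P back into dx
template <bool Scatter>
void colmap(double* x, ConvGeom g, double* P) {
  const long npos = g.npos();
  const long imgvox = static_cast<long>(g.H) * g.W * g.C;
  for (int c = 0; c < g.C; ++c) {
    for (int kw = 0; kw < g.k; ++kw) {
      for (int kh = 0; kh < g.k; ++kh) {
        double* Pcol = P + npos * g.N * (static_cast<long>(c) * g.k * g.k +
                                         static_cast<long>(kw) * g.k + kh);
        for (int n = 0; n < g.N; ++n) {
          double* xc = x + imgvox * n + static_cast<long>(g.H) * g.W * c;
          for (int pw = 0; pw < g.Wo; ++pw) {
            const int w = pw * g.stride + kw - g.pad;
            double* dst = Pcol + npos * n + static_cast<long>(g.Ho) * pw;
            if (w < 0 || w >= g.W) {
              if (!Scatter) std::fill(dst, dst + g.Ho, 0.0);
              continue;
            }
            double* src = xc + static_cast<long>(g.H) * w;
            if (g.stride == 1) {
              const int h0 = kh - g.pad;             // input row of ph = 0
              int ph_lo = std::max(0, -h0);
              int ph_hi = std::min(g.Ho, g.H - h0);  // exclusive
              if (!Scatter) {
                if (ph_lo > 0) std::fill(dst, dst + ph_lo, 0.0);
                if (ph_hi < g.Ho) std::fill(dst + std::max(ph_lo, ph_hi), dst + g.Ho, 0.0);
                if (ph_hi > ph_lo)
                  std::copy(src + h0 + ph_lo, src + h0 + ph_hi, dst + ph_lo);
              } else {
                for (int ph = ph_lo; ph < ph_hi; ++ph) src[h0 + ph] += dst[ph];
              }
            } else {
              for (int ph = 0; ph < g.Ho; ++ph) {
                const int h = ph * g.stride + kh - g.pad;
                const bool in = (h >= 0 && h < g.H);
                if (!Scatter) {
                  dst[ph] = in ? src[h] : 0.0;
                } else if (in) {
                  src[h] += dst[ph];
                }
              }
            }
          }
        }
      }
    }
  }
}

ConvGeom make_geom(const IntegerVector& xdim, int k, int stride, int pad) {
  ConvGeom g;
  g.H = xdim[0]; g.W = xdim[1]; g.C = xdim[2]; g.N = xdim[3];
  g.k = k; g.stride = stride; g.pad = pad;
  g.Ho = (g.H + 2 * pad - k) / stride + 1;
  g.Wo = (g.W + 2 * pad - k) / stride + 1;
  return g;
}

}  // namespace

// [[Rcpp::export]]
List conv_fwd_cpp(NumericVector x, const IntegerVector& xdim,
                  const arma::mat& Wm, const NumericVector& bias,
                  int k, int stride, int pad) {
  ConvGeom g = make_geom(xdim, k, stride, pad);
  const long rows = g.npos() * g.N;
  XPtr<arma::mat> Pp(new arma::mat(rows, static_cast<long>(k) * k * g.C), true);
  arma::mat& P = *Pp;
  colmap<false>(x.begin(), g, P.memptr());
  arma::mat Y = P * Wm;                          // rows x F
  const int F = Wm.n_cols;
  if (bias.size() == static_cast<R_xlen_t>(F)) {
    for (int f = 0; f < F; ++f) Y.col(f) += bias[f];
  }
  // rows are ordered (ph, pw, n); output wants (ph, pw, f, n)
  NumericVector out(rows * F);
  const long npos = g.npos();
  for (int n = 0; n < g.N; ++n) {
    for (int f = 0; f < F; ++f) {
      const double* src = Y.colptr(f) + npos * n;
      std::copy(src, src + npos,
                out.begin() + npos * (f + static_cast<long>(F) * n));
    }
  }
  out.attr("dim") = IntegerVector::create(g.Ho, g.Wo, F, g.N);
  return List::create(_["out"] = out, _["patches"] = Pp);
}

// [[Rcpp::export]]
List conv_bwd_cpp(const NumericVector& dy, SEXP patches,
                  const arma::mat& Wm, const IntegerVector& xdim,
                  int k, int stride, int pad, bool has_bias, bool need_dx) {
  XPtr<arma::mat> Pp(patches);
  const arma::mat& P = *Pp;
  ConvGeom g = make_geom(xdim, k, stride, pad);
  const long npos = g.npos();
  const long rows = npos * g.N;
  const int F = Wm.n_cols;
  arma::mat dYm(rows, F);
  for (int n = 0; n < g.N; ++n) {
    for (int f = 0; f < F; ++f) {
      const double* src = dy.begin() + npos * (f + static_cast<long>(F) * n);
      std::copy(src, src + npos, dYm.colptr(f) + npos * n);
    }
  }
  arma::mat dW = P.t() * dYm;                    // (k2c x F)
  NumericVector db;
  if (has_bias) {
    arma::rowvec s = arma::sum(dYm, 0);
    db = NumericVector(s.begin(), s.end());
  }
  NumericVector dx;
  if (need_dx) {
    arma::mat dP = dYm * Wm.t();                 // rows x k2c
    dx = NumericVector(static_cast<long>(g.H) * g.W * g.C * g.N);
    colmap<true>(dx.begin(), g, dP.memptr());
    dx.attr("dim") = xdim;
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(const NumericVector& x) {
  NumericVector out(no_init(x.size()));
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(const NumericVector& x, const NumericVector& dy) {
  NumericVector dx(no_init(x.size()));
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? dp[i] : 0.0;
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool_fwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                              int s) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / s, Wo = W / s;
  NumericVector out(static_cast<long>(Ho) * Wo * C * N);
  const double inv = 1.0 / (s * s);
  const double* xp = x.begin();
  double* op = out.begin();
  for (long cn = 0; cn < static_cast<long>(C) * N; ++cn) {
    const double* xi = xp + static_cast<long>(H) * W * cn;
    double* oi = op + static_cast<long>(Ho) * Wo * cn;
    for (int pw = 0; pw < Wo; ++pw) {
      for (int ph = 0; ph < Ho; ++ph) {
        double acc = 0;
        for (int j = 0; j < s; ++j) {
          const double* col = xi + static_cast<long>(H) * (pw * s + j) + ph * s;
          for (int i = 0; i < s; ++i) acc += col[i];
        }
        oi[static_cast<long>(Ho) * pw + ph] = acc * inv;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd_cpp(const NumericVector& dy, const IntegerVector& xdim,
                              int s) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / s, Wo = W / s;
  NumericVector dx(static_cast<long>(H) * W * C * N);
  const double inv = 1.0 / (s * s);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (long cn = 0; cn < static_cast<long>(C) * N; ++cn) {
    const double* di = dyp + static_cast<long>(Ho) * Wo * cn;
    double* xi = dxp + static_cast<long>(H) * W * cn;
    for (int pw = 0; pw < Wo; ++pw) {
      for (int ph = 0; ph < Ho; ++ph) {
        const double v = di[static_cast<long>(Ho) * pw + ph] * inv;
        for (int j = 0; j < s; ++j) {
          double* col = xi + static_cast<long>(H) * (pw * s + j) + ph * s;
          for (int i = 0; i < s; ++i) col[i] = v;
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}
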