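// Grouped 3D convolution kernels (im2col + BLAS GEMM).
//
// Array layout follows the package convention (N, T, C, H, W), column-major,
// so the linear index of x[n, t, c, h, w] (0-based) is
//   n + N*(t + T*(c + C*(h + H*w))).
// Weights are stored as (C_out, C_in/groups, kt, kh, kw).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline size_t xidx(int n, int t, int c, int h, int w,
                          int N, int T, int C, int H) {
  return (size_t)n + (size_t)N * ((size_t)t + (size_t)T *
         ((size_t)c + (size_t)C * ((size_t)h + (size_t)H * (size_t)w)));
}

// Fill col (Cg*kt*kh*kw x To*Ho*Wo) from one sample / one channel group.
static void im2col(const double* x, int N, int T, int C, int H, int W,
                   int n, int c0, int Cg, int kt, int kh, int kw,
                   int st, int sh, int sw, int pt, int ph, int pw,
                   int To, int Ho, int Wo, arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        int l = to + To * (ho + Ho * wo);
        double* cp = col.colptr(l);
        for (int iw = 0; iw < kw; ++iw) {
          int wi = wo * sw - pw + iw;
          for (int ih = 0; ih < kh; ++ih) {
            int hi = ho * sh - ph + ih;
            for (int it = 0; it < kt; ++it) {
              int ti = to * st - pt + it;
              bool inside = ti >= 0 && ti < T && hi >= 0 && hi < H &&
                            wi >= 0 && wi < W;
              for (int ci = 0; ci < Cg; ++ci) {
                int k = ci + Cg * (it + kt * (ih + kh * iw));
                cp[k] = inside ? x[xidx(n, ti, c0 + ci, hi, wi, N, T, C, H)]
                               : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add dcol back into gx (adjoint of im2col).
static void col2im(double* gx, int N, int T, int C, int H, int W,
                   int n, int c0, int Cg, int kt, int kh, int kw,
                   int st, int sh, int sw, int pt, int ph, int pw,
                   int To, int Ho, int Wo, const arma::mat& dcol) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int to = 0; to < To; ++to) {
        int l = to + To * (ho + Ho * wo);
        const double* cp = dcol.colptr(l);
        for (int iw = 0; iw < kw; ++iw) {
          int wi = wo * sw - pw + iw;
          if (wi < 0 || wi >= W) continue;
          for (int ih = 0; ih < kh; ++ih) {
            int hi = ho * sh - ph + ih;
            if (hi < 0 || hi >= H) continue;
            for (int it = 0; it < kt; ++it) {
              int ti = to * st - pt + it;
              if (ti < 0 || ti >= T) continue;
              for (int ci = 0; ci < Cg; ++ci) {
                int k = ci + Cg * (it + kt * (ih + kh * iw));
                gx[xidx(n, ti, c0 + ci, hi, wi, N, T, C, H)] += cp[k];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             IntegerVector stride, IntegerVector pad,
                             int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int N = xd[0], T = xd[1], C = xd[2], H = xd[3], W = xd[4];
  int Cout = wd[0], Cg = wd[1], kt = wd[2], kh = wd[3], kw = wd[4];
  int st = stride[0], sh = stride[1], sw = stride[2];
  int pt = pad[0], ph = pad[1], pw = pad[2];
  if (C != Cg * groups) stop("conv3d: input channels (%d) != groups (%d) * kernel channels (%d)", C, groups, Cg);
  if (Cout % groups != 0) stop("conv3d: output channels not divisible by groups");
  int To = (T + 2 * pt - kt) / st + 1;
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  if (To < 1 || Ho < 1 || Wo < 1)
    stop("conv3d: output extent < 1 (input %dx%dx%d, kernel %dx%dx%d)", T, H, W, kt, kh, kw);
  int Coutg = Cout / groups;
  int K = Cg * kt * kh * kw, L = To * Ho * Wo;

  NumericVector y((R_xlen_t)N * To * Cout * Ho * Wo);
  arma::mat Wm(w.begin(), Cout, K, false, true);
  arma::mat col(K, L);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), N, T, C, H, W, n, g * Cg, Cg, kt, kh, kw,
             st, sh, sw, pt, ph, pw, To, Ho, Wo, col);
      arma::mat out = Wm.rows(g * Coutg, (g + 1) * Coutg - 1) * col;
      for (int l = 0; l < L; ++l) {
        int to = l % To, rem = l / To;
        int ho = rem % Ho, wo = rem / Ho;
        for (int co = 0; co < Coutg; ++co) {
          yp[xidx(n, to, g * Coutg + co, ho, wo, N, To, Cout, Ho)] = out(co, l);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(N, To, Cout, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector stride, IntegerVector pad, int groups,
                    bool need_gx, bool need_gw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  int N = xd[0], T = xd[1], C = xd[2], H = xd[3], W = xd[4];
  int Cout = wd[0], Cg = wd[1], kt = wd[2], kh = wd[3], kw = wd[4];
  int st = stride[0], sh = stride[1], sw = stride[2];
  int pt = pad[0], ph = pad[1], pw = pad[2];
  int To = yd[1], Ho = yd[3], Wo = yd[4];
  int Coutg = Cout / groups;
  int K = Cg * kt * kh * kw, L = To * Ho * Wo;

  NumericVector gx((R_xlen_t)x.size());
  NumericVector gw((R_xlen_t)w.size());
  arma::mat Wm(w.begin(), Cout, K, false, true);
  arma::mat gWm(gw.begin(), Cout, K, false, true);
  arma::mat col(K, L);
  arma::mat gyg(Coutg, L);
  const double* gyp = gy.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      for (int l = 0; l < L; ++l) {
        int to = l % To, rem = l / To;
        int ho = rem % Ho, wo = rem / Ho;
        for (int co = 0; co < Coutg; ++co)
          gyg(co, l) = gyp[xidx(n, to, g * Coutg + co, ho, wo, N, To, Cout, Ho)];
      }
      if (need_gw) {
        im2col(x.begin(), N, T, C, H, W, n, g * Cg, Cg, kt, kh, kw,
               st, sh, sw, pt, ph, pw, To, Ho, Wo, col);
        gWm.rows(g * Coutg, (g + 1) * Coutg - 1) += gyg * col.t();
      }
      if (need_gx) {
        arma::mat dcol = Wm.rows(g * Coutg, (g + 1) * Coutg - 1).t() * gyg;
        col2im(gx.begin(), N, T, C, H, W, n, g * Cg, Cg, kt, kh, kw,
               st, sh, sw, pt, ph, pw, To, Ho, Wo, dcol);
      }
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw);
}
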