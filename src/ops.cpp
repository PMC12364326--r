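#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are stored as R arrays with dim = c(H, W, C, N), column-major,
// so the row index h is the fastest-varying one. Convolution weights have
// dim = c(KH, KW, Cin/groups, Cout).

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// valid output index range [lo, hi] for a kernel offset: indices o with
// 0 <= o*stride - pad + k <= in - 1
static inline void valid_range(int in, int out, int stride, int pad, int k,
                               int &lo, int &hi) {
  lo = 0;
  int num = pad - k;
  if (num > 0) lo = (num + stride - 1) / stride;
  hi = out - 1;
  int top = (in - 1 + pad - k) / stride;
  if (top < hi) hi = top;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cig = wd[2], Cout = wd[3];
  if (Cig * groups != C) stop("conv2d: input channels inconsistent with groups");
  const int Cog = Cout / groups;
  const int Ho = out_size(H, KH, stride, pad), Wo = out_size(W, KW, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: output size would be non-positive");
  NumericVector y(Ho * (R_xlen_t)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      for (int ocg = 0; ocg < Cog; ++ocg) {
        const int oc = g * Cog + ocg;
        double *yo = py + ((R_xlen_t)n * Cout + oc) * Ho * Wo;
        const double bias = pb[oc];
        for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i) yo[i] = bias;
        for (int icg = 0; icg < Cig; ++icg) {
          const int ic = g * Cig + icg;
          const double *xi = px + ((R_xlen_t)n * C + ic) * H * W;
          const double *wk = pw + ((R_xlen_t)oc * Cig + icg) * KH * KW;
          for (int kw = 0; kw < KW; ++kw) {
            int wlo, whi;
            valid_range(W, Wo, stride, pad, kw, wlo, whi);
            for (int kh = 0; kh < KH; ++kh) {
              const double wv = wk[kh + kw * KH];
              if (wv == 0.0) continue;
              int hlo, hhi;
              valid_range(H, Ho, stride, pad, kh, hlo, hhi);
              for (int ow = wlo; ow <= whi; ++ow) {
                const int iw = ow * stride - pad + kw;
                const double *xcol = xi + (R_xlen_t)iw * H;
                double *ycol = yo + (R_xlen_t)ow * Ho;
                if (stride == 1) {
                  const double *xs = xcol - pad + kh;
                  for (int oh = hlo; oh <= hhi; ++oh)
                    ycol[oh] += wv * xs[oh];
                } else {
                  for (int oh = hlo; oh <= hhi; ++oh)
                    ycol[oh] += wv * xcol[oh * stride - pad + kh];
                }
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_input(NumericVector gy, NumericVector w,
                                   IntegerVector xdim, int stride, int pad,
                                   int groups) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2], N = gd[3];
  const int KH = wd[0], KW = wd[1], Cig = wd[2];
  const int H = xdim[0], Wd = xdim[1], C = xdim[2];
  const int Cog = Cout / groups;
  NumericVector gx((R_xlen_t)H * Wd * C * N);
  gx.attr("dim") = xdim;
  const double *pg = gy.begin(), *pw = w.begin();
  double *px = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      for (int ocg = 0; ocg < Cog; ++ocg) {
        const int oc = g * Cog + ocg;
        const double *go = pg + ((R_xlen_t)n * Cout + oc) * Ho * Wo;
        for (int icg = 0; icg < Cig; ++icg) {
          const int ic = g * Cig + icg;
          double *xi = px + ((R_xlen_t)n * C + ic) * H * Wd;
          const double *wk = pw + ((R_xlen_t)oc * Cig + icg) * KH * KW;
          for (int kw = 0; kw < KW; ++kw) {
            int wlo, whi;
            valid_range(Wd, Wo, stride, pad, kw, wlo, whi);
            for (int kh = 0; kh < KH; ++kh) {
              const double wv = wk[kh + kw * KH];
              if (wv == 0.0) continue;
              int hlo, hhi;
              valid_range(H, Ho, stride, pad, kh, hlo, hhi);
              for (int ow = wlo; ow <= whi; ++ow) {
                const int iw = ow * stride - pad + kw;
                double *xcol = xi + (R_xlen_t)iw * H;
                const double *gcol = go + (R_xlen_t)ow * Ho;
                if (stride == 1) {
                  double *xs = xcol - pad + kh;
                  for (int oh = hlo; oh <= hhi; ++oh)
                    xs[oh] += wv * gcol[oh];
                } else {
                  for (int oh = hlo; oh <= hhi; ++oh)
                    xcol[oh * stride - pad + kh] += wv * gcol[oh];
                }
              }
            }
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_weight(NumericVector gy, NumericVector x,
                                    IntegerVector wdim, int stride, int pad,
                                    int groups) {
  IntegerVector gd = gy.attr("dim"), xd = x.attr("dim");
  const int Ho = gd[0], Wo = gd[1], Cout = gd[2], N = gd[3];
  const int H = xd[0], W = xd[1], C = xd[2];
  const int KH = wdim[0], KW = wdim[1], Cig = wdim[2];
  const int Cog = Cout / groups;
  NumericVector gw((R_xlen_t)KH * KW * Cig * Cout);
  gw.attr("dim") = wdim;
  const double *pg = gy.begin(), *px = x.begin();
  double *pw = gw.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      for (int ocg = 0; ocg < Cog; ++ocg) {
        const int oc = g * Cog + ocg;
        const double *go = pg + ((R_xlen_t)n * Cout + oc) * Ho * Wo;
        for (int icg = 0; icg < Cig; ++icg) {
          const int ic = g * Cig + icg;
          const double *xi = px + ((R_xlen_t)n * C + ic) * H * W;
          double *wk = pw + ((R_xlen_t)oc * Cig + icg) * KH * KW;
          for (int kw = 0; kw < KW; ++kw) {
            int wlo, whi;
            valid_range(W, Wo, stride, pad, kw, wlo, whi);
            for (int kh = 0; kh < KH; ++kh) {
              int hlo, hhi;
              valid_range(H, Ho, stride, pad, kh, hlo, hhi);
              double acc = 0.0;
              for (int ow = wlo; ow <= whi; ++ow) {
                const int iw = ow * stride - pad + kw;
                const double *xcol = xi + (R_xlen_t)iw * H;
                const double *gcol = go + (R_xlen_t)ow * Ho;
                if (stride == 1) {
                  const double *xs = xcol - pad + kh;
                  for (int oh = hlo; oh <= hhi; ++oh)
                    acc += xs[oh] * gcol[oh];
                } else {
                  for (int oh = hlo; oh <= hhi; ++oh)
                    acc += xcol[oh * stride - pad + kh] * gcol[oh];
                }
              }
              wk[kh + kw * KH] += acc;
            }
          }
        }
      }
    }
  }
  return gw;
}

// 2x2 max pooling, stride 2. Returns the pooled map and the 1-based linear
// index (into x) of each maximum, for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  int *pi = idx.begin();
  R_xlen_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const R_xlen_t base = (R_xlen_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const int ih = 2 * oh, iw = 2 * ow;
        R_xlen_t best = base + (R_xlen_t)iw * H + ih;
        double bv = px[best];
        const R_xlen_t cand[3] = {best + 1, best + H, best + H + 1};
        for (int t = 0; t < 3; ++t)
          if (px[cand[t]] > bv) { bv = px[cand[t]]; best = cand[t]; }
        py[o] = bv;
        pi[o] = (int)(best + 1);
        ++o;
      }
    }
  }
  return List::create(_["value"] = y, _["index"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  const double *pg = gy.begin();
  const int *pi = idx.begin();
  double *px = gx.begin();
  const R_xlen_t m = gy.size();
  for (R_xlen_t i = 0; i < m; ++i) px[pi[i] - 1] += pg[i];
  return gx;
}

// Bilinear resize to (Ho, Wo). Source coordinates follow the half-pixel
// convention src = (dst + 0.5) * in/out - 0.5 (identity when in == out).
// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int oh = 0; oh < Ho; ++oh) {
    double s = (oh + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[oh] = (int)std::floor(s);
    h1[oh] = std::min(h0[oh] + 1, H - 1);
    fh[oh] = s - h0[oh];
  }
  for (int ow = 0; ow < Wo; ++ow) {
    double s = (ow + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[ow] = (int)std::floor(s);
    w1[ow] = std::min(w0[ow] + 1, W - 1);
    fw[ow] = s - w0[ow];
  }
  const double *px = x.begin();
  double *py = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double *xi = px + (R_xlen_t)cn * H * W;
    double *yo = py + (R_xlen_t)cn * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      const double *c0 = xi + (R_xlen_t)w0[ow] * H;
      const double *c1 = xi + (R_xlen_t)w1[ow] * H;
      double *ycol = yo + (R_xlen_t)ow * Ho;
      for (int oh = 0; oh < Ho; ++oh) {
        const double a = (1 - fh[oh]) * c0[h0[oh]] + fh[oh] * c0[h1[oh]];
        const double b = (1 - fh[oh]) * c1[h0[oh]] + fh[oh] * c1[h1[oh]];
        ycol[oh] = (1 - fw[ow]) * a + fw[ow] * b;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> fh(Ho), fw(Wo);
  for (int oh = 0; oh < Ho; ++oh) {
    double s = (oh + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[oh] = (int)std::floor(s);
    h1[oh] = std::min(h0[oh] + 1, H - 1);
    fh[oh] = s - h0[oh];
  }
  for (int ow = 0; ow < Wo; ++ow) {
    double s = (ow + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[ow] = (int)std::floor(s);
    w1[ow] = std::min(w0[ow] + 1, W - 1);
    fw[ow] = s - w0[ow];
  }
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    double *xi = px + (R_xlen_t)cn * H * W;
    const double *go = pg + (R_xlen_t)cn * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      double *c0 = xi + (R_xlen_t)w0[ow] * H;
      double *c1 = xi + (R_xlen_t)w1[ow] * H;
      const double *gcol = go + (R_xlen_t)ow * Ho;
      for (int oh = 0; oh < Ho; ++oh) {
        const double g = gcol[oh];
        c0[h0[oh]] += (1 - fh[oh]) * (1 - fw[ow]) * g;
        c0[h1[oh]] += fh[oh] * (1 - fw[ow]) * g;
        c1[h0[oh]] += (1 - fh[oh]) * fw[ow] * g;
        c1[h1[oh]] += fh[oh] * fw[ow] * g;
      }
    }
  }
  return gx;
}
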