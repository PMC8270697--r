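// Low-level array kernels for the CPU conv-net engine.
// Layout convention everywhere: x is an R array (H, W, C, N), column-major;
// conv weights are (kh, kw, cin_per_group, cout). All backward kernels
// return gradients of a scalar loss w.r.t. their inputs given the gradient
// w.r.t. their output.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (kh*kw*cg rows, Ho*Wo cols) for sample n, group g.
static void im2col(const double* x, int H, int W, int C, int n, int g,
                   int cg, int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  const long HW = (long)H * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int q = ho + Ho * wo;
      const int i0 = ho * stride - pad;
      const int j0 = wo * stride - pad;
      for (int cl = 0; cl < cg; ++cl) {
        const int c = g * cg + cl;
        const double* xc = x + HW * (c + (long)C * n);
        for (int kj = 0; kj < kw; ++kj) {
          const int j = j0 + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int i = i0 + ki;
            const int r = ki + kh * (kj + kw * cl);
            col(r, q) = (i >= 0 && i < H && j >= 0 && j < W)
              ? xc[i + (long)H * j] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back onto the input raster (transpose of im2col).
static void col2im_add(double* gx, int H, int W, int C, int n, int g,
                       int cg, int kh, int kw, int stride, int pad,
                       int Ho, int Wo, const arma::mat& col) {
  const long HW = (long)H * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int q = ho + Ho * wo;
      const int i0 = ho * stride - pad;
      const int j0 = wo * stride - pad;
      for (int cl = 0; cl < cg; ++cl) {
        const int c = g * cg + cl;
        double* xc = gx + HW * (c + (long)C * n);
        for (int kj = 0; kj < kw; ++kj) {
          const int j = j0 + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int i = i0 + ki;
            if (i < 0 || i >= H) continue;
            xc[i + (long)H * j] += col(ki + kh * (kj + kw * cl), q);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = "cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cg = wd[2], Cout = wd[3];
  if (C != cg * groups) stop("conv2d: input channels do not match weight/groups");
  if (Cout % groups != 0) stop("conv2d: out channels not divisible by groups");
  const int cog = Cout / groups;
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: kernel larger than padded input");
  NumericVector y(Ho * (long)Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(kh * kw * cg, (long)Ho * Wo);
  const long HoWo = (long)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, n, g, cg, kh, kw, stride, pad, Ho, Wo, col);
      // weight slab for this group: rows = kh*kw*cg, cols = cog
      arma::mat wm(const_cast<double*>(w.begin()) + (long)kh * kw * cg * (g * cog),
                   kh * kw * cg, cog, false, true);
      arma::mat ym = wm.t() * col;             // (cog, Ho*Wo)
      for (int cl = 0; cl < cog; ++cl) {
        const int c = g * cog + cl;
        double* yc = y.begin() + HoWo * (c + (long)Cout * n);
        const double bc = b.size() > 0 ? b[c] : 0.0;
        for (long q = 0; q < HoWo; ++q) yc[q] = ym(cl, q) + bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = "cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], cg = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int cog = Cout / groups;
  const long HoWo = (long)Ho * Wo;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);
  arma::mat col(kh * kw * cg, HoWo);
  arma::mat gym(cog, HoWo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, n, g, cg, kh, kw, stride, pad, Ho, Wo, col);
      for (int cl = 0; cl < cog; ++cl) {
        const int c = g * cog + cl;
        const double* gyc = gy.begin() + HoWo * (c + (long)Cout * n);
        for (long q = 0; q < HoWo; ++q) gym(cl, q) = gyc[q];
        if (has_bias) {
          double s = 0; for (long q = 0; q < HoWo; ++q) s += gyc[q];
          gb[c] += s;
        }
      }
      arma::mat gwm(gw.begin() + (long)kh * kw * cg * (g * cog),
                    kh * kw * cg, cog, false, true);
      gwm += col * gym.t();
      arma::mat wm(const_cast<double*>(w.begin()) + (long)kh * kw * cg * (g * cog),
                   kh * kw * cg, cog, false, true);
      arma::mat gcol = wm * gym;               // (kh*kw*cg, Ho*Wo)
      col2im_add(gx.begin(), H, W, C, n, g, cg, kh, kw, stride, pad, Ho, Wo, gcol);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Average pooling with window == stride == k.
// [[Rcpp::export(name = "cpp_avgpool_fwd")]]
NumericVector cpp_avgpool_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % k != 0 || W % k != 0) stop("avgpool: size not divisible by window");
  const int Ho = H / k, Wo = W / k;
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (k * k);
  const long HW = (long)H * W, HoWo = (long)Ho * Wo;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = x.begin() + HW * cn;
    double* yc = y.begin() + HoWo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double s = 0;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            s += xc[(ho * k + ki) + (long)H * (wo * k + kj)];
        yc[ho + (long)Ho * wo] = s * inv;
      }
  }
  return y;
}

// [[Rcpp::export(name = "cpp_avgpool_bwd")]]
NumericVector cpp_avgpool_bwd(NumericVector gy, int k, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double inv = 1.0 / (k * k);
  const long HW = (long)H * W, HoWo = (long)Ho * Wo;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* gyc = gy.begin() + HoWo * cn;
    double* gxc = gx.begin() + HW * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double v = gyc[ho + (long)Ho * wo] * inv;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki)
            gxc[(ho * k + ki) + (long)H * (wo * k + kj)] += v;
      }
  }
  return gx;
}

// Max pooling with window == stride == k; returns y and flat argmax indices.
// [[Rcpp::export(name = "cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(NumericVector x, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % k != 0 || W % k != 0) stop("maxpool: size not divisible by window");
  const int Ho = H / k, Wo = W / k;
  NumericVector y((long)Ho * Wo * C * N);
  IntegerVector idx((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const long HW = (long)H * W, HoWo = (long)Ho * Wo;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = x.begin() + HW * cn;
    double* yc = y.begin() + HoWo * cn;
    int* ic = idx.begin() + HoWo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -std::numeric_limits<double>::infinity(); long bi = 0;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            const long p = (ho * k + ki) + (long)H * (wo * k + kj);
            if (xc[p] > best) { best = xc[p]; bi = p; }
          }
        yc[ho + (long)Ho * wo] = best;
        ic[ho + (long)Ho * wo] = (int)(bi + HW * cn);
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_maxpool_bwd")]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx,
                              int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int C = yd[2], N = yd[3];
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (long q = 0; q < (long)gy.size(); ++q) gx[idx[q]] += gy[q];
  return gx;
}

// Nearest-neighbour upsampling by integer factor f.
// [[Rcpp::export(name = "cpp_upsample_fwd")]]
NumericVector cpp_upsample_fwd(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const long HW = (long)H * W, HoWo = (long)Ho * Wo;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = x.begin() + HW * cn;
    double* yc = y.begin() + HoWo * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yc[ho + (long)Ho * wo] = xc[(ho / f) + (long)H * (wo / f)];
  }
  return y;
}

// [[Rcpp::export(name = "cpp_upsample_bwd")]]
NumericVector cpp_upsample_bwd(NumericVector gy, int f) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / f, W = Wo / f;
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const long HW = (long)H * W, HoWo = (long)Ho * Wo;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* gyc = gy.begin() + HoWo * cn;
    double* gxc = gx.begin() + HW * cn;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        gxc[(ho / f) + (long)H * (wo / f)] += gyc[ho + (long)Ho * wo];
  }
  return gx;
}
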