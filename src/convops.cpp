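// Dense kernels for the training engine. Tensors are R arrays in
// column-major (H, W, C, N) layout; weights are (kh, kw, Cin, Cout).
// Convolutions are stride-1 with zero padding and optional dilation,
// implemented as im2col + GEMM so the heavy lifting happens in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + (long)H * (w + (long)W * (c + (long)C * n));
}

// Fill `col` (K x HW, K = kh*kw*Cin) for sample n of x. The innermost
// axial run is contiguous in both source and destination, so it is a
// straight strided copy once the boundary clamp is hoisted out.
static void im2col(const double* x, int H, int W, int C, int n,
                   int kh, int kw, int pad, int dil, arma::mat& col) {
  col.zeros();
  const long K = (long)kh * kw * C;
  double* cm = col.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const long krow = ki + kh * (kj + (long)kw * c);
        const int di = dil * ki - pad, dj = dil * kj - pad;
        const int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
        if (i_lo >= i_hi) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const double* src = x + idx4(i_lo + di, sj, c, n, H, W, C);
          double* dst = cm + krow + K * (i_lo + (long)H * j);
          for (int i = i_lo; i < i_hi; ++i, src += 1, dst += K) *dst = *src;
        }
      }
    }
  }
}

// Scatter-add the columns back into sample n of gx (transpose of im2col).
static void col2im(const arma::mat& col, double* gx, int H, int W, int C,
                   int n, int kh, int kw, int pad, int dil) {
  const long K = (long)kh * kw * C;
  const double* cm = col.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const long krow = ki + kh * (kj + (long)kw * c);
        const int di = dil * ki - pad, dj = dil * kj - pad;
        const int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
        if (i_lo >= i_hi) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          double* dst = gx + idx4(i_lo + di, sj, c, n, H, W, C);
          const double* src = cm + krow + K * (i_lo + (long)H * j);
          for (int i = i_lo; i < i_hi; ++i, dst += 1, src += K) *dst += *src;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector b, int pad, int dil) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int HW = H * W, K = kh * kw * C;
  NumericVector out(Rcpp::no_init((long)HW * Cout * N));
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat col(K, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, kh, kw, pad, dil, col);
    arma::mat o(out.begin() + (long)HW * Cout * n, HW, Cout, false, true);
    o = col.t() * Wm;
    o.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector gy, int pad, int dil) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int HW = H * W, K = kh * kw * C;
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = xdim;
  NumericVector gw((long)K * Cout);
  gw.attr("dim") = wdim;
  NumericVector gb(Cout);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  arma::rowvec gbv(gb.begin(), Cout, false, true);
  arma::mat col(K, HW);
  for (int n = 0; n < N; ++n) {
    const arma::mat gyn(const_cast<double*>(gy.begin()) + (long)HW * Cout * n,
                        HW, Cout, false, true);
    im2col(x.begin(), H, W, C, n, kh, kw, pad, dil, col);
    gWm += col * gyn;
    gbv += arma::sum(gyn, 0);
    arma::mat gcol = Wm * gyn.t();     // K x HW
    col2im(gcol, gx.begin(), H, W, C, n, kh, kw, pad, dil);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and the flat (1-based)
// argmax index into the input for the backward scatter.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((long)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((long)Ho * Wo * C * N);
  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300; long bidx = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              long id = idx4(2 * i + di, 2 * j + dj, c, n, H, W, C);
              if (x[id] > best) { best = x[id]; bidx = id; }
            }
          out[q] = best; arg[q] = (int)(bidx + 1); ++q;
        }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector argmax,
                           IntegerVector xdim) {
  NumericVector gx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (long q = 0; q < gy.size(); ++q) gx[argmax[q] - 1] += gy[q];
  return gx;
}

// Axis interpolation table for 2x bilinear upsampling with half-pixel
// centers (source coordinate of output i is i/2 - 0.25, clamped).
static void up2_table(int n_out, std::vector<int>& i0, std::vector<int>& i1,
                      std::vector<double>& w0) {
  const int n_in = n_out / 2;
  i0.resize(n_out); i1.resize(n_out); w0.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = 0.5 * i - 0.25;
    int lo = (int)std::floor(s);
    double f = s - lo;
    int hi = lo + 1;
    if (lo < 0) lo = 0;
    if (hi > n_in - 1) hi = n_in - 1;
    if (lo > n_in - 1) lo = n_in - 1;
    i0[i] = lo; i1[i] = hi; w0[i] = 1.0 - f;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((long)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> r0, r1, c0, c1; std::vector<double> wr, wc;
  up2_table(Ho, r0, r1, wr);
  up2_table(Wo, c0, c1, wc);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double v =
            wr[i] * (wc[j] * x[idx4(r0[i], c0[j], c, n, H, W, C)] +
                     (1 - wc[j]) * x[idx4(r0[i], c1[j], c, n, H, W, C)]) +
            (1 - wr[i]) * (wc[j] * x[idx4(r1[i], c0[j], c, n, H, W, C)] +
                           (1 - wc[j]) * x[idx4(r1[i], c1[j], c, n, H, W, C)]);
          out[idx4(i, j, c, n, Ho, Wo, C)] = v;
        }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((long)H * W * C * N);
  gx.attr("dim") = xdim;
  std::vector<int> r0, r1, c0, c1; std::vector<double> wr, wc;
  up2_table(Ho, r0, r1, wr);
  up2_table(Wo, c0, c1, wc);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double g = gy[idx4(i, j, c, n, Ho, Wo, C)];
          gx[idx4(r0[i], c0[j], c, n, H, W, C)] += wr[i] * wc[j] * g;
          gx[idx4(r0[i], c1[j], c, n, H, W, C)] += wr[i] * (1 - wc[j]) * g;
          gx[idx4(r1[i], c0[j], c, n, H, W, C)] += (1 - wr[i]) * wc[j] * g;
          gx[idx4(r1[i], c1[j], c, n, H, W, C)] += (1 - wr[i]) * (1 - wc[j]) * g;
        }
  return gx;
}

// [[Rcpp::export]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector out(Rcpp::no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  for (long i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? x[i] : slope * x[i];
  return out;
}

// [[Rcpp::export]]
NumericVector lrelu_bwd(NumericVector x, NumericVector g, double slope) {
  NumericVector out(Rcpp::no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  for (long i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? g[i] : slope * g[i];
  return out;
}

// Single-level tensor Haar split/merge for the spectral pooling path.
// x (H, W, C, N) -> list(LL, LH, HL, HH) each (H/2, W/2, C, N).
// [[Rcpp::export]]
List haar4_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  IntegerVector od = IntegerVector::create(Ho, Wo, C, N);
  NumericVector LL(Rcpp::no_init((long)Ho * Wo * C * N)),
      LH(Rcpp::no_init(LL.size())), HL(Rcpp::no_init(LL.size())),
      HH(Rcpp::no_init(LL.size()));
  LL.attr("dim") = od; LH.attr("dim") = od;
  HL.attr("dim") = od; HH.attr("dim") = od;
  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++q) {
          const double a = x[idx4(2 * i, 2 * j, c, n, H, W, C)];
          const double b = x[idx4(2 * i, 2 * j + 1, c, n, H, W, C)];
          const double cc = x[idx4(2 * i + 1, 2 * j, c, n, H, W, C)];
          const double dd = x[idx4(2 * i + 1, 2 * j + 1, c, n, H, W, C)];
          LL[q] = (a + b + cc + dd) / 2;
          LH[q] = (cc + dd - a - b) / 2;
          HL[q] = (b + dd - a - cc) / 2;
          HH[q] = (a + dd - b - cc) / 2;
        }
  return List::create(_["LL"] = LL, _["LH"] = LH, _["HL"] = HL,
                      _["HH"] = HH);
}

// [[Rcpp::export]]
NumericVector haar4_inv(NumericVector LL, NumericVector LH,
                        NumericVector HL, NumericVector HH,
                        IntegerVector sdim) {
  const int Ho = sdim[0], Wo = sdim[1], C = sdim[2], N = sdim[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector out(Rcpp::no_init((long)H * W * C * N));
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++q) {
          const double ll = LL[q], lh = LH[q], hl = HL[q], hh = HH[q];
          out[idx4(2 * i, 2 * j, c, n, H, W, C)] = (ll - lh - hl + hh) / 2;
          out[idx4(2 * i, 2 * j + 1, c, n, H, W, C)] = (ll - lh + hl - hh) / 2;
          out[idx4(2 * i + 1, 2 * j, c, n, H, W, C)] = (ll + lh - hl - hh) / 2;
          out[idx4(2 * i + 1, 2 * j + 1, c, n, H, W, C)] =
              (ll + lh + hl + hh) / 2;
        }
  return out;
}

// Group normalization, per (group, sample) moments, per-channel affine.
// [[Rcpp::export]]
List gn_fwd(NumericVector x, IntegerVector xdim, NumericVector gamma,
            NumericVector beta, int groups, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int cg = C / groups;
  const long m = (long)H * W * cg;
  NumericVector out(Rcpp::no_init(x.size())), xhat(Rcpp::no_init(x.size()));
  out.attr("dim") = xdim; xhat.attr("dim") = xdim;
  NumericMatrix inv_sd(groups, N);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      const long base = idx4(0, 0, g * cg, n, H, W, C);
      double mu = 0;
      for (long t = 0; t < m; ++t) mu += x[base + t];
      mu /= m;
      double var = 0;
      for (long t = 0; t < m; ++t) {
        const double d = x[base + t] - mu;
        var += d * d;
      }
      var /= m;
      const double isd = 1.0 / std::sqrt(var + eps);
      inv_sd(g, n) = isd;
      for (int c = 0; c < cg; ++c) {
        const double ga = gamma[g * cg + c], be = beta[g * cg + c];
        const long cb = base + (long)H * W * c;
        for (long t = 0; t < (long)H * W; ++t) {
          const double xh = (x[cb + t] - mu) * isd;
          xhat[cb + t] = xh;
          out[cb + t] = ga * xh + be;
        }
      }
    }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List gn_bwd(NumericVector xhat, IntegerVector xdim, NumericVector gamma,
            NumericMatrix inv_sd, NumericVector gy, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int cg = C / groups;
  const long hw = (long)H * W, m = hw * cg;
  NumericVector gx(Rcpp::no_init(xhat.size()));
  gx.attr("dim") = xdim;
  NumericVector ggamma(C), gbeta(C);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      const long base = idx4(0, 0, g * cg, n, H, W, C);
      double s1 = 0, s2 = 0;   // mean(dxhat), mean(dxhat * xhat)
      for (int c = 0; c < cg; ++c) {
        const double ga = gamma[g * cg + c];
        const long cb = base + hw * c;
        double dg = 0, db = 0;
        for (long t = 0; t < hw; ++t) {
          const double dxh = gy[cb + t] * ga;
          s1 += dxh;
          s2 += dxh * xhat[cb + t];
          dg += gy[cb + t] * xhat[cb + t];
          db += gy[cb + t];
        }
        ggamma[g * cg + c] += dg;
        gbeta[g * cg + c] += db;
      }
      s1 /= m; s2 /= m;
      const double isd = inv_sd(g, n);
      for (int c = 0; c < cg; ++c) {
        const double ga = gamma[g * cg + c];
        const long cb = base + hw * c;
        for (long t = 0; t < hw; ++t) {
          gx[cb + t] =
              isd * (gy[cb + t] * ga - s1 - xhat[cb + t] * s2);
        }
      }
    }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}
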