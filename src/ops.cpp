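// Low-level tensor kernels for the restoration/segmentation networks.
// Tensor layout everywhere: R arrays, column-major, dims (H, W, C, N).
// Convolution weights: (kh, kw, Cin, Cout); depthwise weights: (kh, kw, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void check_dims4(const NumericVector& x, const char* what) {
  if (Rf_isNull(x.attr("dim")) || IntegerVector(x.attr("dim")).size() != 4)
    stop("%s must be a 4-D array (H, W, C, N)", what);
}

// ---------------------------------------------------------------------------
// standard convolution via im2col + GEMM
// ---------------------------------------------------------------------------

static void im2col(const double* x, int H, int W, int Cin, int n,
                   int kh, int kw, int stride, int pad, arma::mat& cols) {
  const int Ho = out_dim(H, kh, stride, pad);
  const int Wo = out_dim(W, kw, stride, pad);
  const double* xn = x + (size_t)H * W * Cin * n;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = xn + (size_t)H * W * c;
    for (int s = 0; s < kw; ++s) {
      for (int r = 0; r < kh; ++r) {
        const int q = r + kh * (s + kw * c);
        double* col = cols.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + s;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) col[ho + Ho * wo] = 0.0;
            continue;
          }
          const double* xw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + r;
            col[ho + Ho * wo] = (hi >= 0 && hi < H) ? xw[hi] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  check_dims4(x, "x"); check_dims4(w, "w");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: input has %d channels, weights expect %d", Cin, wd[2]);
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than padded input");
  const int K = kh * kw * Cin;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out(Ho * Wo * (R_xlen_t)Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(Ho * Wo, K);
  const bool has_b = b.size() == Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Cin, n, kh, kw, stride, pad, cols);
    arma::mat on = cols * Wm;  // (HoWo, Cout)
    double* optr = out.begin() + (size_t)Ho * Wo * Cout * n;
    std::memcpy(optr, on.memptr(), sizeof(double) * (size_t)Ho * Wo * Cout);
    if (has_b)
      for (int o = 0; o < Cout; ++o) {
        double* oc = optr + (size_t)Ho * Wo * o;
        for (int p = 0; p < Ho * Wo; ++p) oc[p] += b[o];
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gout,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const int K = kh * kw * Cin;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gW(gw.begin(), K, Cout, false, true);
  arma::mat cols(Ho * Wo, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Cin, n, kh, kw, stride, pad, cols);
    const arma::mat gon(const_cast<double*>(gout.begin()) + (size_t)Ho * Wo * Cout * n,
                        Ho * Wo, Cout, false, true);
    gW += cols.t() * gon;
    arma::mat gcols = gon * Wm.t();  // (HoWo, K)
    double* gxn = gx.begin() + (size_t)H * W * Cin * n;
    for (int c = 0; c < Cin; ++c) {
      double* gxc = gxn + (size_t)H * W * c;
      for (int s = 0; s < kw; ++s)
        for (int r = 0; r < kh; ++r) {
          const int q = r + kh * (s + kw * c);
          const double* col = gcols.colptr(q);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + s;
            if (wi < 0 || wi >= W) continue;
            double* gxw = gxc + (size_t)H * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + r;
              if (hi >= 0 && hi < H) gxw[hi] += col[ho + Ho * wo];
            }
          }
        }
    }
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(gon.col(o));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// depthwise convolution (stride 1)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, NumericVector w, NumericVector b,
                            int pad) {
  check_dims4(x, "x");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv: channel mismatch");
  const int Ho = out_dim(H, kh, 1, pad), Wo = out_dim(W, kw, 1, pad);
  if (Ho < 1 || Wo < 1) stop("dwconv: kernel larger than padded input");
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const bool has_b = b.size() == C;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* oc = out.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const double bc = has_b ? b[c] : 0.0;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bc;
          for (int s = 0; s < kw; ++s) {
            const int wi = wo - pad + s;
            if (wi < 0 || wi >= W) continue;
            for (int r = 0; r < kh; ++r) {
              const int hi = ho - pad + r;
              if (hi < 0 || hi >= H) continue;
              acc += xc[hi + (size_t)H * wi] * wc[r + kh * s];
            }
          }
          oc[ho + (size_t)Ho * wo] = acc;
        }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, NumericVector w, NumericVector gout, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      const double* gc = gout.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* gwc = gw.begin() + (size_t)kh * kw * c;
      double gbc = 0.0;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gc[ho + (size_t)Ho * wo];
          gbc += g;
          for (int s = 0; s < kw; ++s) {
            const int wi = wo - pad + s;
            if (wi < 0 || wi >= W) continue;
            for (int r = 0; r < kh; ++r) {
              const int hi = ho - pad + r;
              if (hi < 0 || hi >= H) continue;
              gxc[hi + (size_t)H * wi] += g * wc[r + kh * s];
              gwc[r + kh * s] += g * xc[hi + (size_t)H * wi];
            }
          }
        }
      gb[c] += gbc;
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// modulated deformable 3x3 convolution (stride 1, pad 1)
// offsets: (H, W, 18, N) with channels (2t, 2t+1) = (dy, dx) for tap
// t = r + 3*s, r,s in 0..2; mask: (H, W, 9, N), multiplicative per tap.
// ---------------------------------------------------------------------------

static inline double bil_sample(const double* xc, int H, int W, double py, double px) {
  if (py <= -1.0 || py >= (double)H || px <= -1.0 || px >= (double)W) return 0.0;
  const int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
  const double ly = py - y0, lx = px - x0;
  double v = 0.0;
  if (y0 >= 0 && x0 >= 0)             v += (1 - ly) * (1 - lx) * xc[y0 + H * x0];
  if (y0 >= 0 && x0 + 1 < W)          v += (1 - ly) * lx       * xc[y0 + H * (x0 + 1)];
  if (y0 + 1 < H && x0 >= 0)          v += ly * (1 - lx)       * xc[y0 + 1 + H * x0];
  if (y0 + 1 < H && x0 + 1 < W)       v += ly * lx             * xc[y0 + 1 + H * (x0 + 1)];
  return v;
}

static void deform_cols(const double* x, const double* off, const double* mask,
                        int H, int W, int Cin, int n, arma::mat& cols) {
  const size_t HW = (size_t)H * W;
  const double* xn = x + HW * Cin * n;
  const double* offn = off + HW * 18 * n;
  const double* mn = mask + HW * 9 * n;
  for (int t = 0; t < 9; ++t) {
    const int r = t % 3, s = t / 3;
    const double* oy = offn + HW * (2 * t);
    const double* ox = offn + HW * (2 * t + 1);
    const double* mt = mn + HW * t;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const size_t p = i + (size_t)H * j;
        const double py = i + (r - 1) + oy[p];
        const double px = j + (s - 1) + ox[p];
        const double m = mt[p];
        for (int c = 0; c < Cin; ++c)
          cols(p, t + 9 * c) = m * bil_sample(xn + HW * c, H, W, py, px);
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_deform_fw(NumericVector x, NumericVector off, NumericVector mask,
                            NumericVector w, NumericVector b) {
  check_dims4(x, "x");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int K = 9 * Cin;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out((R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat cols((size_t)H * W, K);
  const bool has_b = b.size() == Cout;
  for (int n = 0; n < N; ++n) {
    deform_cols(x.begin(), off.begin(), mask.begin(), H, W, Cin, n, cols);
    arma::mat on = cols * Wm;
    double* optr = out.begin() + (size_t)H * W * Cout * n;
    std::memcpy(optr, on.memptr(), sizeof(double) * (size_t)H * W * Cout);
    if (has_b)
      for (int o = 0; o < Cout; ++o) {
        double* oc = optr + (size_t)H * W * o;
        for (size_t p = 0; p < (size_t)H * W; ++p) oc[p] += b[o];
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_deform_bw(NumericVector x, NumericVector off, NumericVector mask,
                   NumericVector w, NumericVector gout) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int K = 9 * Cin;
  const size_t HW = (size_t)H * W;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gx(x.size());     gx.attr("dim") = xd;
  NumericVector goff(off.size()); goff.attr("dim") = off.attr("dim");
  NumericVector gmask(mask.size()); gmask.attr("dim") = mask.attr("dim");
  NumericVector gw(w.size());     gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gW(gw.begin(), K, Cout, false, true);
  arma::mat cols(HW, K);
  for (int n = 0; n < N; ++n) {
    deform_cols(x.begin(), off.begin(), mask.begin(), H, W, Cin, n, cols);
    const arma::mat gon(const_cast<double*>(gout.begin()) + HW * Cout * n,
                        HW, Cout, false, true);
    gW += cols.t() * gon;
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(gon.col(o));
    arma::mat gcols = gon * Wm.t();  // (HW, K)
    const double* xn = x.begin() + HW * Cin * n;
    const double* offn = off.begin() + HW * 18 * n;
    const double* mn = mask.begin() + HW * 9 * n;
    double* gxn = gx.begin() + HW * Cin * n;
    double* goffn = goff.begin() + HW * 18 * n;
    double* gmn = gmask.begin() + HW * 9 * n;
    for (int t = 0; t < 9; ++t) {
      const int r = t % 3, s = t / 3;
      const double* oy = offn + HW * (2 * t);
      const double* ox = offn + HW * (2 * t + 1);
      const double* mt = mn + HW * t;
      double* goy = goffn + HW * (2 * t);
      double* gox = goffn + HW * (2 * t + 1);
      double* gmt = gmn + HW * t;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const size_t p = i + (size_t)H * j;
          const double py = i + (r - 1) + oy[p];
          const double px = j + (s - 1) + ox[p];
          const double m = mt[p];
          if (py <= -1.0 || py >= (double)H || px <= -1.0 || px >= (double)W) continue;
          const int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
          const double ly = py - y0, lx = px - x0;
          const bool v00 = (y0 >= 0 && x0 >= 0), v01 = (y0 >= 0 && x0 + 1 < W);
          const bool v10 = (y0 + 1 < H && x0 >= 0), v11 = (y0 + 1 < H && x0 + 1 < W);
          double gpy = 0.0, gpx = 0.0;
          for (int c = 0; c < Cin; ++c) {
            const double g = gcols(p, t + 9 * c);
            if (g == 0.0) continue;
            const double* xc = xn + HW * c;
            double* gxc = gxn + HW * c;
            const double a00 = v00 ? xc[y0 + H * x0] : 0.0;
            const double a01 = v01 ? xc[y0 + H * (x0 + 1)] : 0.0;
            const double a10 = v10 ? xc[y0 + 1 + H * x0] : 0.0;
            const double a11 = v11 ? xc[y0 + 1 + H * (x0 + 1)] : 0.0;
            const double val = (1 - ly) * (1 - lx) * a00 + (1 - ly) * lx * a01 +
                               ly * (1 - lx) * a10 + ly * lx * a11;
            gmt[p] += val * g;
            const double gm = m * g;
            if (v00) gxc[y0 + H * x0]           += (1 - ly) * (1 - lx) * gm;
            if (v01) gxc[y0 + H * (x0 + 1)]     += (1 - ly) * lx * gm;
            if (v10) gxc[y0 + 1 + H * x0]       += ly * (1 - lx) * gm;
            if (v11) gxc[y0 + 1 + H * (x0 + 1)] += ly * lx * gm;
            gpy += gm * ((1 - lx) * (a10 - a00) + lx * (a11 - a01));
            gpx += gm * ((1 - ly) * (a01 - a00) + ly * (a11 - a10));
          }
          goy[p] += gpy;
          gox[p] += gpx;
        }
    }
  }
  return List::create(_["gx"] = gx, _["goff"] = goff, _["gmask"] = gmask,
                      _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// bilinear x2 upsampling (align_corners = FALSE, border-clamped)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_up2_fw(NumericVector x) {
  check_dims4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> y0v(Ho), y1v(Ho); std::vector<double> lyv(Ho);
  std::vector<int> x0v(Wo), x1v(Wo); std::vector<double> lxv(Wo);
  for (int i = 0; i < Ho; ++i) {
    double sy = (i + 0.5) / 2.0 - 0.5;
    if (sy < 0) sy = 0;
    if (sy > H - 1) sy = H - 1;
    y0v[i] = (int)std::floor(sy); y1v[i] = std::min(y0v[i] + 1, H - 1);
    lyv[i] = sy - y0v[i];
  }
  for (int j = 0; j < Wo; ++j) {
    double sx = (j + 0.5) / 2.0 - 0.5;
    if (sx < 0) sx = 0;
    if (sx > W - 1) sx = W - 1;
    x0v[j] = (int)std::floor(sx); x1v[j] = std::min(x0v[j] + 1, W - 1);
    lxv[j] = sx - x0v[j];
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* oc = out.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double ly = lyv[i], lx = lxv[j];
          oc[i + (size_t)Ho * j] =
            (1 - ly) * (1 - lx) * xc[y0v[i] + (size_t)H * x0v[j]] +
            (1 - ly) * lx       * xc[y0v[i] + (size_t)H * x1v[j]] +
            ly * (1 - lx)       * xc[y1v[i] + (size_t)H * x0v[j]] +
            ly * lx             * xc[y1v[i] + (size_t)H * x1v[j]];
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_up2_bw(NumericVector gout) {
  IntegerVector gd = gout.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gout.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        double sx = (j + 0.5) / 2.0 - 0.5;
        if (sx < 0) sx = 0;
        if (sx > W - 1) sx = W - 1;
        const int x0 = (int)std::floor(sx), x1 = std::min(x0 + 1, W - 1);
        const double lx = sx - x0;
        for (int i = 0; i < Ho; ++i) {
          double sy = (i + 0.5) / 2.0 - 0.5;
          if (sy < 0) sy = 0;
          if (sy > H - 1) sy = H - 1;
          const int y0 = (int)std::floor(sy), y1 = std::min(y0 + 1, H - 1);
          const double ly = sy - y0;
          const double g = gc[i + (size_t)Ho * j];
          gxc[y0 + (size_t)H * x0] += (1 - ly) * (1 - lx) * g;
          gxc[y0 + (size_t)H * x1] += (1 - ly) * lx * g;
          gxc[y1 + (size_t)H * x0] += ly * (1 - lx) * g;
          gxc[y1 + (size_t)H * x1] += ly * lx * g;
        }
      }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  check_dims4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: H and W must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      const double* xc = x.begin() + base;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int i = 2 * ho, j = 2 * wo;
          size_t best = i + (size_t)H * j;
          double bv = xc[best];
          const size_t cand[3] = {i + 1 + (size_t)H * j, i + (size_t)H * (j + 1),
                                  i + 1 + (size_t)H * (j + 1)};
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
          out[(R_xlen_t)ho + Ho * ((R_xlen_t)wo + Wo * ((R_xlen_t)c + (R_xlen_t)C * n))] = bv;
          idx[q++] = (R_xlen_t)(base + best);
        }
    }
  // note: idx stored in (ho fastest? we filled q sequentially over ho inner) — order:
  // loops are n, c, wo, ho with q incrementing; out index matches (ho,wo,c,n) only if
  // filled in same order. They are: for fixed (n,c), wo outer, ho inner -> linear
  // index ho + Ho*wo, matching. Good.
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector gout, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t q = 0; q < gout.size(); ++q) gx[idx[q]] += gout[q];
  return gx;
}
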