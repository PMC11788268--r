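// Low-level numerical kernels: exact Euclidean distance transform,
// im2col/GEMM convolution with manual backward, 2x2 pooling, nearest
// upsampling and separable resampling. All image arrays are column-major
// H x W x C (channels last), matching R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (lower envelope of parabolas).
// f: sampled function, d: output, n: length. Positions are 0..n-1.
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { // no finite parabola yet
      v[0] = q;
      continue;
    }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) { // entire row infinite
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in physical units) from every pixel to the
// nearest feature pixel centre. feature: H x W integer matrix (nonzero =
// feature). Anisotropic spacing (sy, sx) supported by scaling each pass.
// Returns +Inf everywhere when no feature pixel exists.
// [[Rcpp::export]]
NumericMatrix cpp_edt(IntegerMatrix feature, double sy, double sx) {
  int H = feature.nrow(), W = feature.ncol();
  NumericMatrix out(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  std::vector<int> v(std::max(H, W));
  std::vector<double> z(std::max(H, W) + 1);
  double sx2 = sx * sx, sy2 = sy * sy;

  // pass 1: along rows (x direction), squared distances scaled by sx^2
  NumericMatrix g(H, W);
  for (int i = 0; i < H; i++) {
    for (int j = 0; j < W; j++) f[j] = feature(i, j) != 0 ? 0.0 : INF;
    dt1d(f.data(), d.data(), W, v.data(), z.data());
    for (int j = 0; j < W; j++) g(i, j) = d[j] == INF ? INF : sx2 * d[j];
  }
  // pass 2: along columns (y direction)
  for (int j = 0; j < W; j++) {
    for (int i = 0; i < H; i++) f[i] = g(i, j) == INF ? INF : g(i, j) / sy2;
    dt1d(f.data(), d.data(), H, v.data(), z.data());
    for (int i = 0; i < H; i++) out(i, j) = d[i] == INF ? INF : std::sqrt(sy2 * d[i]);
  }
  return out;
}

// Foreground pixels with at least one 4-connected background neighbour.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary4(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; j++) {
    for (int i = 0; i < H; i++) {
      if (mask(i, j) == 0) continue;
      bool b = false;
      if (i > 0 && mask(i - 1, j) == 0) b = true;
      else if (i < H - 1 && mask(i + 1, j) == 0) b = true;
      else if (j > 0 && mask(i, j - 1) == 0) b = true;
      else if (j < W - 1 && mask(i, j + 1) == 0) b = true;
      out(i, j) = b ? 1 : 0;
    }
  }
  return out;
}

static void im2col_f(const double* x, int H, int W, int C, int K, int pad,
                     arma::fmat& col) {
  // col: (H*W) x (K*K*C); col(i + H*j, u + K*v + K*K*c) = x(i+u-pad, j+v-pad, c)
  col.zeros();
  for (int c = 0; c < C; c++) {
    const double* xc = x + (size_t)H * W * c;
    for (int v = 0; v < K; v++) {
      for (int u = 0; u < K; u++) {
        int q = u + K * v + K * K * c;
        float* cq = col.colptr(q);
        int i0 = std::max(0, pad - u), i1 = std::min(H, H + pad - u);
        for (int j = 0; j < W; j++) {
          int js = j + v - pad;
          if (js < 0 || js >= W) continue;
          const double* src = xc + (size_t)H * js + (u - pad);
          float* dst = cq + (size_t)H * j;
          for (int i = i0; i < i1; i++) dst[i] = (float)src[i];
        }
      }
    }
  }
}

static void col2im_f(const arma::fmat& dcol, int H, int W, int C, int K,
                     int pad, double* dx) {
  for (int c = 0; c < C; c++) {
    double* xc = dx + (size_t)H * W * c;
    for (int v = 0; v < K; v++) {
      for (int u = 0; u < K; u++) {
        int q = u + K * v + K * K * c;
        const float* cq = dcol.colptr(q);
        int i0 = std::max(0, pad - u), i1 = std::min(H, H + pad - u);
        for (int j = 0; j < W; j++) {
          int js = j + v - pad;
          if (js < 0 || js >= W) continue;
          double* dst = xc + (size_t)H * js + (u - pad);
          const float* src = cq + (size_t)H * j;
          for (int i = i0; i < i1; i++) dst[i] += src[i];
        }
      }
    }
  }
}

// Same-padding 2D convolution (cross-correlation, the deep-learning
// convention) via im2col + single-precision GEMM. x: H x W x Cin;
// wmat: (K*K*Cin) x Cout; bias: length Cout.
// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericMatrix wmat,
                                 NumericVector bias, int H, int W, int Cin,
                                 int K) {
  int pad = (K - 1) / 2;
  int Cout = wmat.ncol();
  int HW = H * W;
  arma::fmat col(HW, K * K * Cin);
  im2col_f(x.begin(), H, W, Cin, K, pad, col);
  arma::fmat Wm(K * K * Cin, Cout);
  std::copy(wmat.begin(), wmat.end(), Wm.begin());
  arma::fmat y = col * Wm;
  NumericVector out((size_t)HW * Cout);
  for (int co = 0; co < Cout; co++) {
    const float* yc = y.colptr(co);
    double* oc = out.begin() + (size_t)HW * co;
    double b = bias[co];
    for (int p = 0; p < HW; p++) oc[p] = yc[p] + b;
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// Backward pass of cpp_conv2d_forward. dy: H x W x Cout.
// Returns list(dx, dw, db).
// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericMatrix wmat, NumericVector dy,
                         int H, int W, int Cin, int K) {
  int pad = (K - 1) / 2;
  int Cout = wmat.ncol();
  int HW = H * W;
  arma::fmat col(HW, K * K * Cin);
  im2col_f(x.begin(), H, W, Cin, K, pad, col);
  arma::fmat dyM(HW, Cout);
  std::copy(dy.begin(), dy.end(), dyM.begin());
  arma::fmat Wm(K * K * Cin, Cout);
  std::copy(wmat.begin(), wmat.end(), Wm.begin());

  arma::fmat dW = col.t() * dyM;
  arma::frowvec db = arma::sum(dyM, 0);
  arma::fmat dcol = dyM * Wm.t();
  NumericVector dx(x.size());
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im_f(dcol, H, W, Cin, K, pad, dx.begin());
  dx.attr("dim") = IntegerVector::create(H, W, Cin);

  NumericMatrix dWout(K * K * Cin, Cout);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbout(Cout);
  for (int co = 0; co < Cout; co++) dbout[co] = db[co];
  return List::create(_["dx"] = dx, _["dw"] = dWout, _["db"] = dbout);
}

// Fused batch-norm (batch of one: statistics over H*W per channel) + ReLU.
// training: use batch stats and update running buffers; else running stats.
// [[Rcpp::export]]
List cpp_bn_relu_forward(NumericVector z, NumericVector gamma,
                         NumericVector beta, NumericVector rmean,
                         NumericVector rvar, bool training, double momentum,
                         double eps, int H, int W, int C) {
  int HW = H * W;
  NumericVector a((size_t)HW * C), xhat((size_t)HW * C), inv_sd(C);
  NumericVector nrm(clone(rmean)), nrv(clone(rvar));
  for (int c = 0; c < C; c++) {
    const double* zc = z.begin() + (size_t)HW * c;
    double mu, v;
    if (training) {
      double s = 0;
      for (int p = 0; p < HW; p++) s += zc[p];
      mu = s / HW;
      double s2 = 0;
      for (int p = 0; p < HW; p++) { double d = zc[p] - mu; s2 += d * d; }
      v = s2 / HW;
      nrm[c] = (1 - momentum) * nrm[c] + momentum * mu;
      nrv[c] = (1 - momentum) * nrv[c] + momentum * v;
    } else {
      mu = rmean[c];
      v = rvar[c];
    }
    double isd = 1.0 / std::sqrt(v + eps);
    inv_sd[c] = isd;
    double g = gamma[c], be = beta[c];
    double* xc = xhat.begin() + (size_t)HW * c;
    double* ac = a.begin() + (size_t)HW * c;
    for (int p = 0; p < HW; p++) {
      double xh = (zc[p] - mu) * isd;
      xc[p] = xh;
      double y = g * xh + be;
      ac[p] = y > 0 ? y : 0.0;
    }
  }
  a.attr("dim") = IntegerVector::create(H, W, C);
  xhat.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["a"] = a, _["xhat"] = xhat, _["inv_sd"] = inv_sd,
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// Backward of cpp_bn_relu_forward. `a` is the forward output (its zeros
// define the ReLU mask). Returns list(dz, dgamma, dbeta).
// [[Rcpp::export]]
List cpp_bn_relu_backward(NumericVector da, NumericVector a,
                          NumericVector xhat, NumericVector inv_sd,
                          NumericVector gamma, bool training, int H, int W,
                          int C) {
  int HW = H * W;
  NumericVector dz((size_t)HW * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; c++) {
    const double* dac = da.begin() + (size_t)HW * c;
    const double* ac = a.begin() + (size_t)HW * c;
    const double* xc = xhat.begin() + (size_t)HW * c;
    double* dzc = dz.begin() + (size_t)HW * c;
    double sum_dy = 0, sum_dyx = 0;
    for (int p = 0; p < HW; p++) {
      double dyp = ac[p] > 0 ? dac[p] : 0.0;
      dzc[p] = dyp;  // temporarily store masked dy
      sum_dy += dyp;
      sum_dyx += dyp * xc[p];
    }
    dgamma[c] = sum_dyx;
    dbeta[c] = sum_dy;
    double g = gamma[c] * inv_sd[c];
    if (training) {
      double m_dy = sum_dy / HW, m_dyx = sum_dyx / HW;
      for (int p = 0; p < HW; p++)
        dzc[p] = g * (dzc[p] - m_dy - xc[p] * m_dyx);
    } else {
      for (int p = 0; p < HW; p++) dzc[p] = g * dzc[p];
    }
  }
  dz.attr("dim") = IntegerVector::create(H, W, C);
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Plain ReLU (for norm = "none" blocks); backward masks on the
// pre-activation sign.
// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector z) {
  NumericVector a(clone(z));
  for (R_xlen_t i = 0; i < a.size(); i++) if (a[i] < 0) a[i] = 0;
  return a;
}

// 2x2 max pooling with stride 2; H and W must be even.
// Returns list(y, idx) where idx holds 1-based linear indices of argmaxes.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x, int H, int W, int C) {
  int oh = H / 2, ow = W / 2;
  NumericVector y((size_t)oh * ow * C);
  IntegerVector idx((size_t)oh * ow * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; c++) {
    for (int j = 0; j < ow; j++) {
      for (int i = 0; i < oh; i++) {
        size_t best = 0;
        double bv = -INF;
        for (int dj = 0; dj < 2; dj++) {
          for (int di = 0; di < 2; di++) {
            size_t lin = (size_t)(2 * i + di) + (size_t)H * (2 * j + dj) +
                         (size_t)H * W * c;
            if (xp[lin] > bv) { bv = xp[lin]; best = lin; }
          }
        }
        size_t o = (size_t)i + (size_t)oh * j + (size_t)oh * ow * c;
        y[o] = bv;
        idx[o] = (int)best + 1;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx, int H,
                                    int W, int C) {
  NumericVector dx((size_t)H * W * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  for (R_xlen_t k = 0; k < dy.size(); k++) dx[idx[k] - 1] += dy[k];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x, int H, int W, int C) {
  int oh = 2 * H, ow = 2 * W;
  NumericVector y((size_t)oh * ow * C);
  for (int c = 0; c < C; c++) {
    for (int j = 0; j < ow; j++) {
      for (int i = 0; i < oh; i++) {
        y[(size_t)i + (size_t)oh * j + (size_t)oh * ow * c] =
            x[(size_t)(i / 2) + (size_t)H * (j / 2) + (size_t)H * W * c];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy, int H, int W, int C) {
  // H, W are the *input* (coarse) dims; dy is 2H x 2W x C.
  NumericVector dx((size_t)H * W * C);
  std::fill(dx.begin(), dx.end(), 0.0);
  int oh = 2 * H, ow = 2 * W;
  for (int c = 0; c < C; c++) {
    for (int j = 0; j < ow; j++) {
      for (int i = 0; i < oh; i++) {
        dx[(size_t)(i / 2) + (size_t)H * (j / 2) + (size_t)H * W * c] +=
            dy[(size_t)i + (size_t)oh * j + (size_t)oh * ow * c];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Bilinear resampling with endpoint alignment: output corners sample input
// corners, so resizing to the same size is the identity and linear ramps are
// preserved exactly.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int H, int W, int C, int oh,
                                  int ow) {
  NumericVector y((size_t)oh * ow * C);
  std::vector<int> i0(oh), i1(oh);
  std::vector<double> wi(oh);
  for (int i = 0; i < oh; i++) {
    double s = oh > 1 ? (double)i * (H - 1) / (oh - 1) : (H - 1) / 2.0;
    i0[i] = std::min((int)std::floor(s), H - 1);
    i1[i] = std::min(i0[i] + 1, H - 1);
    wi[i] = s - i0[i];
  }
  std::vector<int> j0(ow), j1(ow);
  std::vector<double> wj(ow);
  for (int j = 0; j < ow; j++) {
    double s = ow > 1 ? (double)j * (W - 1) / (ow - 1) : (W - 1) / 2.0;
    j0[j] = std::min((int)std::floor(s), W - 1);
    j1[j] = std::min(j0[j] + 1, W - 1);
    wj[j] = s - j0[j];
  }
  for (int c = 0; c < C; c++) {
    const double* xc = x.begin() + (size_t)H * W * c;
    double* yc = y.begin() + (size_t)oh * ow * c;
    for (int j = 0; j < ow; j++) {
      for (int i = 0; i < oh; i++) {
        double a = xc[i0[i] + (size_t)H * j0[j]];
        double b = xc[i1[i] + (size_t)H * j0[j]];
        double d = xc[i0[i] + (size_t)H * j1[j]];
        double e = xc[i1[i] + (size_t)H * j1[j]];
        double top = a * (1 - wi[i]) + b * wi[i];
        double bot = d * (1 - wi[i]) + e * wi[i];
        yc[i + (size_t)oh * j] = top * (1 - wj[j]) + bot * wj[j];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  return y;
}

// Area-weighted resampling (exact block mean for integer reduction factors).
// [[Rcpp::export]]
NumericVector cpp_resize_area(NumericVector x, int H, int W, int C, int oh,
                              int ow) {
  NumericVector y((size_t)oh * ow * C);
  double ry = (double)H / oh, rx = (double)W / ow;
  for (int c = 0; c < C; c++) {
    const double* xc = x.begin() + (size_t)H * W * c;
    double* yc = y.begin() + (size_t)oh * ow * c;
    for (int j = 0; j < ow; j++) {
      double x0 = j * rx, x1 = (j + 1) * rx;
      for (int i = 0; i < oh; i++) {
        double y0 = i * ry, y1 = (i + 1) * ry;
        double acc = 0.0, area = 0.0;
        for (int jj = (int)std::floor(x0); jj < (int)std::ceil(x1); jj++) {
          double wx = std::min((double)jj + 1, x1) - std::max((double)jj, x0);
          if (wx <= 0) continue;
          for (int ii = (int)std::floor(y0); ii < (int)std::ceil(y1); ii++) {
            double wy = std::min((double)ii + 1, y1) - std::max((double)ii, y0);
            if (wy <= 0) continue;
            acc += wx * wy * xc[std::min(ii, H - 1) + (size_t)H * std::min(jj, W - 1)];
            area += wx * wy;
          }
        }
        yc[i + (size_t)oh * j] = acc / area;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  return y;
}
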