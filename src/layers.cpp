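// Native building blocks for the 2-D U-Net and the volume geometry helpers.
// Batches of transaxial planes are stored as column-major double arrays with
// dim = c(H, W, C, N); single volumes as c(nx, ny, nz).  Convolutions use
// im2col + BLAS gemm; the transposed convolution is implemented as the exact
// adjoint of a stride-2 convolution (so output size is 2H x 2W for 3x3/s2/p1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;

static inline Rcpp::IntegerVector arr_dim(const NumericVector& x) {
  return x.attr("dim");
}

static NumericVector make_arr4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * (R_xlen_t)c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector make_iarr4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * (R_xlen_t)c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// cols(k*k*C, Ho*Wo); row index ky + k*kx + k*k*c, col index oy + Ho*ox.
static void im2col(const double* im, int H, int W, int C,
                   int k, int pad, int stride, mat& cols) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  cols.zeros(k * k * C, (size_t)Ho * Wo);
  for (int ox = 0; ox < Wo; ++ox) {
    const int x0 = ox * stride - pad;
    for (int oy = 0; oy < Ho; ++oy) {
      const int y0 = oy * stride - pad;
      double* dst = cols.colptr((size_t)oy + (size_t)Ho * ox);
      for (int c = 0; c < C; ++c) {
        const double* imc = im + (size_t)H * W * c;
        for (int kx = 0; kx < k; ++kx) {
          const int x = x0 + kx;
          if (x < 0 || x >= W) continue;
          const double* imcx = imc + (size_t)H * x;
          for (int ky = 0; ky < k; ++ky) {
            const int y = y0 + ky;
            if (y < 0 || y >= H) continue;
            dst[ky + k * kx + k * k * c] = imcx[y];
          }
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add columns back into the H x W x C image
static void col2im(const mat& cols, int H, int W, int C,
                   int k, int pad, int stride, double* im) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  for (int ox = 0; ox < Wo; ++ox) {
    const int x0 = ox * stride - pad;
    for (int oy = 0; oy < Ho; ++oy) {
      const int y0 = oy * stride - pad;
      const double* src = cols.colptr((size_t)oy + (size_t)Ho * ox);
      for (int c = 0; c < C; ++c) {
        double* imc = im + (size_t)H * W * c;
        for (int kx = 0; kx < k; ++kx) {
          const int x = x0 + kx;
          if (x < 0 || x >= W) continue;
          double* imcx = imc + (size_t)H * x;
          for (int ky = 0; ky < k; ++ky) {
            const int y = y0 + ky;
            if (y < 0 || y >= H) continue;
            imcx[y] += src[ky + k * kx + k * k * c];
          }
        }
      }
    }
  }
}

// x: [H,W,Ci,N]; w: [k,k,Ci,Co]; b: [Co]; stride-1 'same' conv when pad=(k-1)/2
// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                          int pad) {
  IntegerVector dx = arr_dim(x), dw = arr_dim(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int k = dw[0], Co = dw[3];
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  NumericVector y = make_arr4(Ho, Wo, Co, N);
  const mat Wt(const_cast<double*>(w.begin()), k * k * Ci, Co, false, true);
  const rowvec bv(const_cast<double*>(b.begin()), Co, false, true);
  mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, k, pad, 1, cols);
    mat Y(y.begin() + (size_t)Ho * Wo * Co * n, (size_t)Ho * Wo, Co, false, true);
    Y = cols.t() * Wt;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector dy, int pad) {
  IntegerVector dx_ = arr_dim(x), dw_ = arr_dim(w);
  const int H = dx_[0], W = dx_[1], Ci = dx_[2], N = dx_[3];
  const int k = dw_[0], Co = dw_[3];
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  NumericVector dx = make_arr4(H, W, Ci, N);
  NumericVector dw = make_arr4(k, k, Ci, Co);
  NumericVector db(Co);
  const mat Wt(const_cast<double*>(w.begin()), k * k * Ci, Co, false, true);
  mat dWt(dw.begin(), k * k * Ci, Co, false, true);
  rowvec dbv(db.begin(), Co, false, true);
  mat cols;
  for (int n = 0; n < N; ++n) {
    const mat dY(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Co * n,
                 (size_t)Ho * Wo, Co, false, true);
    im2col(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, k, pad, 1, cols);
    dWt += cols * dY;
    dbv += sum(dY, 0);
    mat dcols = Wt * dY.t();
    col2im(dcols, H, W, Ci, k, pad, 1, dx.begin() + (size_t)H * W * Ci * n);
  }
  return List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                      Rcpp::Named("db") = db);
}

// transposed conv, kernel 3, stride 2, output 2H x 2W.
// x: [H,W,Ci,N]; w stored as the adjoint stride-2 conv weight: [3,3,Co,Ci]
// [[Rcpp::export]]
NumericVector cpp_convt_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = arr_dim(x), dw = arr_dim(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int Co = dw[2];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make_arr4(Ho, Wo, Co, N);
  const mat Wt(const_cast<double*>(w.begin()), 9 * Co, Ci, false, true);
  for (int n = 0; n < N; ++n) {
    const mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * Ci * n,
                 (size_t)H * W, Ci, false, true);
    mat Z = Wt * Xm.t();  // (9*Co) x (H*W)
    double* yp = y.begin() + (size_t)Ho * Wo * Co * n;
    col2im(Z, Ho, Wo, Co, 3, 1, 2, yp);
    for (int c = 0; c < Co; ++c) {
      double* yc = yp + (size_t)Ho * Wo * c;
      const double bc = b[c];
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] += bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = arr_dim(x), dw_ = arr_dim(w);
  const int H = dx_[0], W = dx_[1], Ci = dx_[2], N = dx_[3];
  const int Co = dw_[2];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx = make_arr4(H, W, Ci, N);
  NumericVector dw = make_arr4(3, 3, Co, Ci);
  NumericVector db(Co);
  const mat Wt(const_cast<double*>(w.begin()), 9 * Co, Ci, false, true);
  mat dWt(dw.begin(), 9 * Co, Ci, false, true);
  mat dZ;
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (size_t)Ho * Wo * Co * n;
    im2col(dyp, Ho, Wo, Co, 3, 1, 2, dZ);
    const mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * Ci * n,
                 (size_t)H * W, Ci, false, true);
    mat dXm(dx.begin() + (size_t)H * W * Ci * n, (size_t)H * W, Ci, false, true);
    dXm = dZ.t() * Wt;  // (H*W) x Ci
    dWt += dZ * Xm;
    for (int c = 0; c < Co; ++c) {
      const double* dyc = dyp + (size_t)Ho * Wo * c;
      double s = 0.0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += dyc[i];
      db[c] += s;
    }
  }
  return List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                      Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2; idx stores the flat offset of the argmax within
// the input plane (per channel/sample), for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x) {
  IntegerVector d = arr_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make_arr4(Ho, Wo, C, N);
  IntegerVector idx = make_iarr4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int ox = 0; ox < Wo; ++ox) {
        for (int oy = 0; oy < Ho; ++oy) {
          int best = 2 * oy + H * 2 * ox;
          double bv = xp[best];
          const int cand[3] = {2 * oy + 1 + H * 2 * ox,
                               2 * oy + H * (2 * ox + 1),
                               2 * oy + 1 + H * (2 * ox + 1)};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          yp[oy + Ho * ox] = bv;
          ip[oy + Ho * ox] = best;
        }
      }
    }
  }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = arr_dim(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = make_arr4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int* ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dxp[ip[i]] += dyp[i];
    }
  }
  return dx;
}

// batch normalization over (H, W, N) per channel
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector rmean, NumericVector rvar,
               double momentum, double eps, bool training) {
  IntegerVector d = arr_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t M = (size_t)H * W;
  NumericVector y = make_arr4(H, W, C, N);
  NumericVector mu(C), invstd(C), rm(C), rv(C);
  for (int c = 0; c < C; ++c) {
    double m, is;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + M * (c + (size_t)C * n);
        for (size_t i = 0; i < M; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
      }
      const double cnt = (double)M * N;
      m = s / cnt;
      double var = s2 / cnt - m * m;
      if (var < 0) var = 0;
      is = 1.0 / std::sqrt(var + eps);
      rm[c] = (1.0 - momentum) * rmean[c] + momentum * m;
      rv[c] = (1.0 - momentum) * rvar[c] + momentum * var;
    } else {
      m = rmean[c];
      is = 1.0 / std::sqrt(rvar[c] + eps);
      rm[c] = rmean[c];
      rv[c] = rvar[c];
    }
    mu[c] = m;
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + M * (c + (size_t)C * n);
      double* yp = y.begin() + M * (c + (size_t)C * n);
      for (size_t i = 0; i < M; ++i) yp[i] = g * (xp[i] - m) * is + b;
    }
  }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("mean") = mu,
                      Rcpp::Named("invstd") = invstd,
                      Rcpp::Named("rmean") = rm, Rcpp::Named("rvar") = rv);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector dy, NumericVector x, NumericVector gamma,
               NumericVector mu, NumericVector invstd) {
  IntegerVector d = arr_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t M = (size_t)H * W;
  const double cnt = (double)M * N;
  NumericVector dx = make_arr4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], g = gamma[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + M * (c + (size_t)C * n);
      const double* dyp = dy.begin() + M * (c + (size_t)C * n);
      for (size_t i = 0; i < M; ++i) {
        sdy += dyp[i];
        sdyx += dyp[i] * (xp[i] - m) * is;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + M * (c + (size_t)C * n);
      const double* dyp = dy.begin() + M * (c + (size_t)C * n);
      double* dxp = dx.begin() + M * (c + (size_t)C * n);
      for (size_t i = 0; i < M; ++i) {
        const double xh = (xp[i] - m) * is;
        dxp[i] = g * is * (dyp[i] - sdy / cnt - xh * sdyx / cnt);
      }
    }
  }
  return List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dgamma") = dgamma,
                      Rcpp::Named("dbeta") = dbeta);
}

// separable 3-D Gaussian blur, zero boundary, kernel truncated at 4 sigma
static void blur_axis(std::vector<double>& v, int n0, int n1, int n2,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (double& kv : ker) kv /= s;
  const int dims[3] = {n0, n1, n2};
  const size_t strides[3] = {1, (size_t)n0, (size_t)n0 * n1};
  const int na = dims[axis];
  const size_t sa = strides[axis];
  std::vector<double> line(na);
  // iterate over all lines along `axis`
  int ob[2], k = 0;
  int oaxes[2];
  for (int a = 0; a < 3; ++a) if (a != axis) oaxes[k++] = a;
  for (ob[1] = 0; ob[1] < dims[oaxes[1]]; ++ob[1]) {
    for (ob[0] = 0; ob[0] < dims[oaxes[0]]; ++ob[0]) {
      const size_t base = (size_t)ob[0] * strides[oaxes[0]] +
                          (size_t)ob[1] * strides[oaxes[1]];
      for (int i = 0; i < na; ++i) line[i] = v[base + sa * i];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        const int lo = std::max(0, i - r), hi = std::min(na - 1, i + r);
        for (int j = lo; j <= hi; ++j) acc += line[j] * ker[j - i + r];
        v[base + sa * i] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector vol, NumericVector sigma_vox) {
  IntegerVector d = arr_dim(vol);
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, d[0], d[1], d[2], 0, sigma_vox[0]);
  blur_axis(v, d[0], d[1], d[2], 1, sigma_vox[1]);
  blur_axis(v, d[0], d[1], d[2], 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = d;
  return out;
}

// resample a volume onto a new grid; world coord of voxel i = origin + i*spacing
// method: 0 = trilinear (clamp-to-edge), 1 = nearest neighbour
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, NumericVector spacing,
                             NumericVector origin, IntegerVector out_dim,
                             NumericVector out_spacing, NumericVector out_origin,
                             int method) {
  IntegerVector d = arr_dim(vol);
  const int nx = d[0], ny = d[1], nz = d[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out(Rcpp::Dimension(ox, oy, oz));
  const double* v = vol.begin();
  auto at = [&](int i, int j, int k) -> double {
    return v[(size_t)i + (size_t)nx * j + (size_t)nx * ny * k];
  };
  for (int k = 0; k < oz; ++k) {
    const double wz = out_origin[2] + k * out_spacing[2];
    const double fz = (wz - origin[2]) / spacing[2];
    for (int j = 0; j < oy; ++j) {
      const double wy = out_origin[1] + j * out_spacing[1];
      const double fy = (wy - origin[1]) / spacing[1];
      for (int i = 0; i < ox; ++i) {
        const double wx = out_origin[0] + i * out_spacing[0];
        const double fx = (wx - origin[0]) / spacing[0];
        double val;
        if (method == 1) {
          int ii = (int)std::lround(fx), jj = (int)std::lround(fy),
              kk = (int)std::lround(fz);
          ii = std::min(std::max(ii, 0), nx - 1);
          jj = std::min(std::max(jj, 0), ny - 1);
          kk = std::min(std::max(kk, 0), nz - 1);
          val = at(ii, jj, kk);
        } else {
          double cx = std::min(std::max(fx, 0.0), (double)(nx - 1));
          double cy = std::min(std::max(fy, 0.0), (double)(ny - 1));
          double cz = std::min(std::max(fz, 0.0), (double)(nz - 1));
          const int i0 = std::min((int)std::floor(cx), nx - 2 >= 0 ? nx - 2 : 0);
          const int j0 = std::min((int)std::floor(cy), ny - 2 >= 0 ? ny - 2 : 0);
          const int k0 = std::min((int)std::floor(cz), nz - 2 >= 0 ? nz - 2 : 0);
          const int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
                    k1 = std::min(k0 + 1, nz - 1);
          const double tx = cx - i0, ty = cy - j0, tz = cz - k0;
          const double c00 = at(i0, j0, k0) * (1 - tx) + at(i1, j0, k0) * tx;
          const double c10 = at(i0, j1, k0) * (1 - tx) + at(i1, j1, k0) * tx;
          const double c01 = at(i0, j0, k1) * (1 - tx) + at(i1, j0, k1) * tx;
          const double c11 = at(i0, j1, k1) * (1 - tx) + at(i1, j1, k1) * tx;
          const double c0 = c00 * (1 - ty) + c10 * ty;
          const double c1 = c01 * (1 - ty) + c11 * ty;
          val = c0 * (1 - tz) + c1 * tz;
        }
        out[(size_t)i + (size_t)ox * j + (size_t)ox * oy * k] = val;
      }
    }
  }
  return out;
}

// warp a stack of channels by a shared in-plane displacement field:
// out(y, x, c) = img(y + dy(y,x), x + dx(y,x), c), borders clamped
// [[Rcpp::export]]
NumericVector cpp_warp2d(NumericVector img, NumericVector dxf, NumericVector dyf,
                         int method) {
  IntegerVector d = arr_dim(img);
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out(Rcpp::Dimension(H, W, C));
  for (int c = 0; c < C; ++c) {
    const double* im = img.begin() + (size_t)H * W * c;
    double* op = out.begin() + (size_t)H * W * c;
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        double sy = y + dyf[y + (size_t)H * x];
        double sx = x + dxf[y + (size_t)H * x];
        sy = std::min(std::max(sy, 0.0), (double)(H - 1));
        sx = std::min(std::max(sx, 0.0), (double)(W - 1));
        double val;
        if (method == 1) {
          val = im[(int)std::lround(sy) + (size_t)H * (int)std::lround(sx)];
        } else {
          const int y0 = std::min((int)std::floor(sy), H - 2 >= 0 ? H - 2 : 0);
          const int x0 = std::min((int)std::floor(sx), W - 2 >= 0 ? W - 2 : 0);
          const double ty = sy - y0, tx = sx - x0;
          const double v00 = im[y0 + (size_t)H * x0];
          const double v10 = im[y0 + 1 + (size_t)H * x0];
          const double v01 = im[y0 + (size_t)H * (x0 + 1)];
          const double v11 = im[y0 + 1 + (size_t)H * (x0 + 1)];
          val = (v00 * (1 - ty) + v10 * ty) * (1 - tx) +
                (v01 * (1 - ty) + v11 * ty) * tx;
        }
        op[y + (size_t)H * x] = val;
      }
    }
  }
  return out;
}
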