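// Low-level dense 3D tensor kernels used by the encoder-decoder network and the
// resampling step: im2col-based 3D convolution (forward + backward), separable
// factor-2 trilinear up/down sampling with exact adjoints, and generic
// trilinear/nearest grid resampling. Arrays are R numeric arrays in channel-first
// layout dim = c(C, X, Y, Z); 3D volumes are dim = c(X, Y, Z).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector &x, int &C, int &X, int &Y, int &Z) {
  if (Rf_isNull(x.attr("dim"))) stop("expected a 4D array, got a dimensionless vector");
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (C, X, Y, Z), got %d dims", (int)d.size());
  C = d[0]; X = d[1]; Y = d[2]; Z = d[3];
}

static inline int conv_out_dim(int n, int k, int s) {
  int p = (k - 1) / 2;
  return (n + 2 * p - k) / s + 1;
}

// Gather receptive fields into a (C*k^3) x Nout matrix; zero padding, stride s.
static arma::mat im2col(const double *x, int C, int X, int Y, int Z,
                        int k, int s, int Xo, int Yo, int Zo) {
  const int p = (k - 1) / 2;
  arma::mat col(C * k * k * k, (arma::uword)Xo * Yo * Zo, arma::fill::zeros);
  arma::uword j = 0;
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox, ++j) {
        double *cptr = col.colptr(j);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * s - p + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * s - p + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * s - p + kx;
              if (ix < 0 || ix >= X) continue;
              const double *src = x + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              double *dst = cptr + (size_t)C * (kx + (size_t)k * (ky + (size_t)k * kz));
              std::memcpy(dst, src, C * sizeof(double));
            }
          }
        }
      }
  return col;
}

// Adjoint of im2col: scatter-add columns back into the input grid.
static void col2im(const arma::mat &col, double *gx, int C, int X, int Y, int Z,
                   int k, int s, int Xo, int Yo, int Zo) {
  const int p = (k - 1) / 2;
  arma::uword j = 0;
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox, ++j) {
        const double *cptr = col.colptr(j);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * s - p + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * s - p + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * s - p + kx;
              if (ix < 0 || ix >= X) continue;
              double *dst = gx + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              const double *src = cptr + (size_t)C * (kx + (size_t)k * (ky + (size_t)k * kz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b, int stride) {
  int C, X, Y, Z;
  get_dims4(x, C, X, Y, Z);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weights must be a 5D array (Cout, Cin, k, k, k)");
  const int Cout = wd[0], Cin = wd[1], k = wd[2];
  if (Cin != C) stop("input has %d channels but weights expect %d", C, Cin);
  const int Xo = conv_out_dim(X, k, stride), Yo = conv_out_dim(Y, k, stride),
            Zo = conv_out_dim(Z, k, stride);
  arma::mat col = im2col(x.begin(), C, X, Y, Z, k, stride, Xo, Yo, Zo);
  arma::mat W(w.begin(), Cout, (arma::uword)Cin * k * k * k, false, true);
  arma::mat out = W * col;
  out.each_col() += arma::vec(b.begin(), Cout);
  NumericVector y(out.begin(), out.end());
  y.attr("dim") = IntegerVector::create(Cout, Xo, Yo, Zo);
  return y;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gy, int stride) {
  int C, X, Y, Z;
  get_dims4(x, C, X, Y, Z);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[0], Cin = wd[1], k = wd[2];
  const int k3 = k * k * k;
  const int Xo = conv_out_dim(X, k, stride), Yo = conv_out_dim(Y, k, stride),
            Zo = conv_out_dim(Z, k, stride);
  arma::mat col = im2col(x.begin(), C, X, Y, Z, k, stride, Xo, Yo, Zo);
  arma::mat W(w.begin(), Cout, (arma::uword)Cin * k3, false, true);
  arma::mat G(gy.begin(), Cout, (arma::uword)Xo * Yo * Zo, false, true);

  arma::mat gW = G * col.t();
  arma::vec gb = arma::sum(G, 1);

  NumericVector gx(x.size());
  if (stride == 1) {
    // Input gradient as a correlation of the output gradient with the
    // spatially flipped, transposed kernel: one GEMM instead of scatter-add.
    arma::mat Wt(Cin, (arma::uword)Cout * k3);
    for (int kidx = 0; kidx < k3; ++kidx) {
      const int kx = kidx % k, ky = (kidx / k) % k, kz = kidx / (k * k);
      const int flip = (k - 1 - kx) + k * ((k - 1 - ky) + k * (k - 1 - kz));
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wt(ci, co + (arma::uword)Cout * kidx) = W(co, ci + (arma::uword)Cin * flip);
    }
    arma::mat gcolY = im2col(gy.begin(), Cout, Xo, Yo, Zo, k, 1, Xo, Yo, Zo);
    arma::mat GX = Wt * gcolY;
    std::memcpy(gx.begin(), GX.memptr(), GX.n_elem * sizeof(double));
  } else {
    arma::mat gcol = W.t() * G;
    col2im(gcol, gx.begin(), C, X, Y, Z, k, stride, Xo, Yo, Zo);
  }
  gx.attr("dim") = x.attr("dim");

  NumericVector gw(gW.begin(), gW.end());
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Factor-2 linear interpolation along one axis of a (pre, n, post) view,
// voxel-center (align_corners = false) convention: out[2i] = .25 in[i-1] + .75 in[i],
// out[2i+1] = .75 in[i] + .25 in[i+1], edges clamped.
static void axis_up2(const double *x, double *y, size_t pre, int n, size_t post) {
  for (size_t q = 0; q < post; ++q)
    for (int i = 0; i < n; ++i) {
      const int il = i > 0 ? i - 1 : 0, ir = i < n - 1 ? i + 1 : n - 1;
      const double *xi = x + pre * (i + (size_t)n * q);
      const double *xl = x + pre * (il + (size_t)n * q);
      const double *xr = x + pre * (ir + (size_t)n * q);
      double *ye = y + pre * ((size_t)2 * i + (size_t)2 * n * q);
      double *yo = ye + pre;
      for (size_t c = 0; c < pre; ++c) {
        ye[c] = 0.25 * xl[c] + 0.75 * xi[c];
        yo[c] = 0.75 * xi[c] + 0.25 * xr[c];
      }
    }
}

static void axis_up2_adj(const double *gy, double *gx, size_t pre, int n, size_t post) {
  for (size_t q = 0; q < post; ++q)
    for (int i = 0; i < n; ++i) {
      const int il = i > 0 ? i - 1 : 0, ir = i < n - 1 ? i + 1 : n - 1;
      const double *ge = gy + pre * ((size_t)2 * i + (size_t)2 * n * q);
      const double *go = ge + pre;
      double *xi = gx + pre * (i + (size_t)n * q);
      double *xl = gx + pre * (il + (size_t)n * q);
      double *xr = gx + pre * (ir + (size_t)n * q);
      for (size_t c = 0; c < pre; ++c) {
        xl[c] += 0.25 * ge[c];
        xi[c] += 0.75 * ge[c] + 0.75 * go[c];
        xr[c] += 0.25 * go[c];
      }
    }
}

// [[Rcpp::export(name = ".upsample2_fw")]]
NumericVector upsample2_fw(NumericVector x) {
  int C, X, Y, Z;
  get_dims4(x, C, X, Y, Z);
  std::vector<double> t1((size_t)C * 2 * X * Y * Z), t2((size_t)C * 2 * X * 2 * Y * Z);
  NumericVector y((R_xlen_t)C * 2 * X * 2 * Y * 2 * Z);
  axis_up2(x.begin(), t1.data(), C, X, (size_t)Y * Z);
  axis_up2(t1.data(), t2.data(), (size_t)C * 2 * X, Y, Z);
  axis_up2(t2.data(), y.begin(), (size_t)C * 2 * X * 2 * Y, Z, 1);
  y.attr("dim") = IntegerVector::create(C, 2 * X, 2 * Y, 2 * Z);
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
NumericVector upsample2_bw(NumericVector gy) {
  int C, X2, Y2, Z2;
  get_dims4(gy, C, X2, Y2, Z2);
  const int X = X2 / 2, Y = Y2 / 2, Z = Z2 / 2;
  std::vector<double> t2((size_t)C * X2 * Y2 * Z, 0.0), t1((size_t)C * X2 * Y * Z, 0.0);
  NumericVector gx((R_xlen_t)C * X * Y * Z);
  axis_up2_adj(gy.begin(), t2.data(), (size_t)C * X2 * Y2, Z, 1);
  axis_up2_adj(t2.data(), t1.data(), (size_t)C * X2, Y, Z);
  axis_up2_adj(t1.data(), gx.begin(), C, X, (size_t)Y * Z);
  gx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return gx;
}

// Resample a single 3D volume between voxel grids with given spacings (mm),
// voxel-center convention. method: 0 = trilinear, 1 = nearest neighbour.
// [[Rcpp::export(name = ".resample3d")]]
NumericVector resample3d(NumericVector x, NumericVector spacing_in,
                         NumericVector spacing_out, IntegerVector out_dim, int method) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3D volume");
  const int X = d[0], Y = d[1], Z = d[2];
  const int Xo = out_dim[0], Yo = out_dim[1], Zo = out_dim[2];
  NumericVector y((R_xlen_t)Xo * Yo * Zo);
  const double *xs = x.begin();
  double *ys = y.begin();
  const double rx = spacing_out[0] / spacing_in[0], ry = spacing_out[1] / spacing_in[1],
               rz = spacing_out[2] / spacing_in[2];
  size_t j = 0;
  for (int oz = 0; oz < Zo; ++oz) {
    double cz = (oz + 0.5) * rz - 0.5;
    cz = std::min(std::max(cz, 0.0), (double)(Z - 1));
    for (int oy = 0; oy < Yo; ++oy) {
      double cy = (oy + 0.5) * ry - 0.5;
      cy = std::min(std::max(cy, 0.0), (double)(Y - 1));
      for (int ox = 0; ox < Xo; ++ox, ++j) {
        double cx = (ox + 0.5) * rx - 0.5;
        cx = std::min(std::max(cx, 0.0), (double)(X - 1));
        if (method == 1) {
          const int ix = (int)std::lround(cx), iy = (int)std::lround(cy), iz = (int)std::lround(cz);
          ys[j] = xs[ix + (size_t)X * (iy + (size_t)Y * iz)];
        } else {
          const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
          const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
                    z1 = std::min(z0 + 1, Z - 1);
          const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          double acc = 0.0;
          const int xi[2] = {x0, x1}, yi[2] = {y0, y1}, zi[2] = {z0, z1};
          const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
          for (int a = 0; a < 2; ++a)
            for (int bq = 0; bq < 2; ++bq)
              for (int cq = 0; cq < 2; ++cq) {
                const double wgt = wx[a] * wy[bq] * wz[cq];
                if (wgt != 0.0)
                  acc += wgt * xs[xi[a] + (size_t)X * (yi[bq] + (size_t)Y * zi[cq])];
              }
          ys[j] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  return y;
}

// Instance normalization over the spatial voxels of a (C, N) channel-first
// view: per-channel zero mean, unit variance, learnable scale/shift.
// [[Rcpp::export(name = ".inorm_fw")]]
List inorm_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector d = x.attr("dim");
  const int C = d[0];
  const R_xlen_t N = x.size() / C;
  std::vector<double> mu(C, 0.0), m2(C, 0.0);
  const double *xs = x.begin();
  for (R_xlen_t v = 0; v < N; ++v) {
    const double *xv = xs + (size_t)C * v;
    for (int c = 0; c < C; ++c) {
      mu[c] += xv[c];
      m2[c] += xv[c] * xv[c];
    }
  }
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) {
    mu[c] /= N;
    istd[c] = 1.0 / std::sqrt(m2[c] / N - mu[c] * mu[c] + eps);
  }
  NumericVector y(x.size()), xhat(x.size());
  double *ys = y.begin(), *hs = xhat.begin();
  for (R_xlen_t v = 0; v < N; ++v) {
    const double *xv = xs + (size_t)C * v;
    double *yv = ys + (size_t)C * v, *hv = hs + (size_t)C * v;
    for (int c = 0; c < C; ++c) {
      hv[c] = (xv[c] - mu[c]) * istd[c];
      yv[c] = gamma[c] * hv[c] + beta[c];
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export(name = ".inorm_bw")]]
List inorm_bw_cpp(NumericVector gy, NumericVector xhat, NumericVector istd,
                  NumericVector gamma) {
  IntegerVector d = gy.attr("dim");
  const int C = d[0];
  const R_xlen_t N = gy.size() / C;
  std::vector<double> s1(C, 0.0), s2(C, 0.0), gg(C, 0.0), gb(C, 0.0);
  const double *gs = gy.begin(), *hs = xhat.begin();
  for (R_xlen_t v = 0; v < N; ++v) {
    const double *gv = gs + (size_t)C * v, *hv = hs + (size_t)C * v;
    for (int c = 0; c < C; ++c) {
      const double gh = gv[c] * gamma[c];
      s1[c] += gh;
      s2[c] += gh * hv[c];
      gg[c] += gv[c] * hv[c];
      gb[c] += gv[c];
    }
  }
  for (int c = 0; c < C; ++c) { s1[c] /= N; s2[c] /= N; }
  NumericVector gx(gy.size());
  double *xs = gx.begin();
  for (R_xlen_t v = 0; v < N; ++v) {
    const double *gv = gs + (size_t)C * v, *hv = hs + (size_t)C * v;
    double *xv = xs + (size_t)C * v;
    for (int c = 0; c < C; ++c)
      xv[c] = istd[c] * (gv[c] * gamma[c] - s1[c] - hv[c] * s2[c]);
  }
  gx.attr("dim") = gy.attr("dim");
  return List::create(_["gx"] = gx,
                      _["ggamma"] = NumericVector(gg.begin(), gg.end()),
                      _["gbeta"] = NumericVector(gb.begin(), gb.end()));
}
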