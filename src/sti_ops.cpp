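// Low-level volumetric kernels: 3x3x3 "same" convolution (im2col + GEMM),
// 2x average pooling, and grid resampling.  Arrays are column-major with
// dims (d1, d2, d3[, channels]) matching R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const double* x, int d1, int d2, int d3, int cin) {
  const int n = d1 * d2 * d3;
  arma::mat col(n, 27 * cin, arma::fill::zeros);
  int colj = 0;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)n * c;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          double* dst = col.colptr(colj++);
          for (int k = 0; k < d3; ++k) {
            int ks = k + dk;
            if (ks < 0 || ks >= d3) continue;
            for (int j = 0; j < d2; ++j) {
              int js = j + dj;
              if (js < 0 || js >= d2) continue;
              int i0 = std::max(0, -di), i1 = std::min(d1, d1 - di);
              const double* src = xc + (size_t)(i0 + di) + (size_t)d1 * (js + (size_t)d2 * ks);
              double* out = dst + (size_t)i0 + (size_t)d1 * (j + (size_t)d2 * k);
              for (int i = i0; i < i1; ++i) *out++ = *src++;
            }
          }
        }
  }
  return col;
}

// weights w: dims (3,3,3,cin,cout) flattened column-major -> (27*cin) x cout
// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2];
  int cin = (xd.size() == 4) ? xd[3] : 1;
  int cout = wd[4];
  if (wd[3] != cin) stop("conv3d: channel mismatch");
  arma::mat col = im2col3(x.begin(), d1, d2, d3, cin);
  arma::mat W(w.begin(), 27 * cin, cout, false);
  arma::mat out = col * W;
  out.each_row() += arma::rowvec(b.begin(), cout, false);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(d1, d2, d3, cout);
  return res;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2];
  int cin = (xd.size() == 4) ? xd[3] : 1;
  int cout = wd[4];
  const int n = d1 * d2 * d3;
  arma::mat col = im2col3(x.begin(), d1, d2, d3, cin);
  arma::mat W(w.begin(), 27 * cin, cout, false);
  arma::mat G(gout.begin(), n, cout, false);
  arma::mat gw = col.t() * G;                 // (27*cin) x cout
  arma::rowvec gb = arma::sum(G, 0);
  arma::mat gcol = G * W.t();                 // n x (27*cin)
  // col2im: scatter-add shifted slices back
  NumericVector gx(n * cin);
  gx.attr("dim") = (xd.size() == 4)
    ? IntegerVector::create(d1, d2, d3, cin)
    : IntegerVector::create(d1, d2, d3);
  int colj = 0;
  for (int c = 0; c < cin; ++c) {
    double* xc = gx.begin() + (size_t)n * c;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          const double* src0 = gcol.colptr(colj++);
          for (int k = 0; k < d3; ++k) {
            int ks = k + dk;
            if (ks < 0 || ks >= d3) continue;
            for (int j = 0; j < d2; ++j) {
              int js = j + dj;
              if (js < 0 || js >= d2) continue;
              int i0 = std::max(0, -di), i1 = std::min(d1, d1 - di);
              double* dst = xc + (size_t)(i0 + di) + (size_t)d1 * (js + (size_t)d2 * ks);
              const double* src = src0 + (size_t)i0 + (size_t)d1 * (j + (size_t)d2 * k);
              for (int i = i0; i < i1; ++i) *dst++ += *src++;
            }
          }
        }
  }
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export(name = ".avgpool3d_fwd")]]
NumericVector avgpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2];
  int c = (xd.size() == 4) ? xd[3] : 1;
  if (d1 % 2 || d2 % 2 || d3 % 2) stop("avgpool3d: dims must be even");
  int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  NumericVector out((size_t)o1 * o2 * o3 * c);
  const double* px = x.begin();
  double* po = out.begin();
  for (int cc = 0; cc < c; ++cc)
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i) {
          double s = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                s += px[(size_t)(2 * i + di) + (size_t)d1 * ((2 * j + dj) +
                        (size_t)d2 * ((2 * k + dk) + (size_t)d3 * cc))];
          po[(size_t)i + (size_t)o1 * (j + (size_t)o2 * (k + (size_t)o3 * cc))] = s / 8.0;
        }
  out.attr("dim") = (xd.size() == 4)
    ? IntegerVector::create(o1, o2, o3, c)
    : IntegerVector::create(o1, o2, o3);
  return out;
}

// [[Rcpp::export(name = ".avgpool3d_bwd")]]
NumericVector avgpool3d_bwd(NumericVector gout, IntegerVector in_dim) {
  int d1 = in_dim[0], d2 = in_dim[1], d3 = in_dim[2];
  int c = (in_dim.size() == 4) ? in_dim[3] : 1;
  int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  NumericVector gx((size_t)d1 * d2 * d3 * c);
  const double* pg = gout.begin();
  double* px = gx.begin();
  for (int cc = 0; cc < c; ++cc)
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i) {
          double g = pg[(size_t)i + (size_t)o1 * (j + (size_t)o2 * (k + (size_t)o3 * cc))] / 8.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                px[(size_t)(2 * i + di) + (size_t)d1 * ((2 * j + dj) +
                   (size_t)d2 * ((2 * k + dk) + (size_t)d3 * cc))] = g;
        }
  gx.attr("dim") = in_dim;
  return gx;
}

// Resample a single 3D volume to out_dim.  scale[d] gives input voxels per
// output voxel; voxel-center alignment x_in = (i_out + 0.5) * scale - 0.5.
// [[Rcpp::export(name = ".resample3d")]]
NumericVector resample3d(NumericVector x, IntegerVector out_dim,
                         NumericVector scale, bool nearest) {
  IntegerVector xd = x.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2];
  int o1 = out_dim[0], o2 = out_dim[1], o3 = out_dim[2];
  if (o1 <= 0 || o2 <= 0 || o3 <= 0) stop("resample3d: zero-size output");
  NumericVector out((size_t)o1 * o2 * o3);
  const double* px = x.begin();
  double* po = out.begin();
  auto clampi = [](int v, int lo, int hi) { return std::min(std::max(v, lo), hi); };
  for (int k = 0; k < o3; ++k) {
    double zk = (k + 0.5) * scale[2] - 0.5;
    for (int j = 0; j < o2; ++j) {
      double yj = (j + 0.5) * scale[1] - 0.5;
      for (int i = 0; i < o1; ++i) {
        double xi = (i + 0.5) * scale[0] - 0.5;
        double v;
        if (nearest) {
          int ii = clampi((int)std::lround(xi), 0, d1 - 1);
          int jj = clampi((int)std::lround(yj), 0, d2 - 1);
          int kk = clampi((int)std::lround(zk), 0, d3 - 1);
          v = px[(size_t)ii + (size_t)d1 * (jj + (size_t)d2 * kk)];
        } else {
          int i0 = clampi((int)std::floor(xi), 0, d1 - 1);
          int j0 = clampi((int)std::floor(yj), 0, d2 - 1);
          int k0 = clampi((int)std::floor(zk), 0, d3 - 1);
          int i1 = clampi(i0 + 1, 0, d1 - 1);
          int j1 = clampi(j0 + 1, 0, d2 - 1);
          int k1 = clampi(k0 + 1, 0, d3 - 1);
          double fx = std::min(std::max(xi - i0, 0.0), 1.0);
          double fy = std::min(std::max(yj - j0, 0.0), 1.0);
          double fz = std::min(std::max(zk - k0, 0.0), 1.0);
          auto at = [&](int a, int b, int cc) {
            return px[(size_t)a + (size_t)d1 * (b + (size_t)d2 * cc)];
          };
          double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
          double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
          double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
          double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          v = c0 * (1 - fz) + c1 * fz;
        }
        po[(size_t)i + (size_t)o1 * (j + (size_t)o2 * k)] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(o1, o2, o3);
  return out;
}
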