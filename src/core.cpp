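// Compiled kernels for 3D volume processing.
//
// Conventions shared with the R side:
//  - arrays are column-major (R layout), linear index = i + nx*(j + ny*k)
//    with 0-based i,j,k;
//  - physical position of voxel (i,j,k) = origin + (i,j,k)*spacing (0-based);
//  - rigid maps are passed as a 3x3 matrix A and offset b acting on physical
//    points: q = A p + b (pull convention: output-space point -> input-space).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector data, IntegerVector dim, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(data.size());
  if (radius == 0) { std::copy(data.begin(), data.end(), out.begin()); return out; }
  const int w = 2 * radius + 1;
  std::vector<double> buf;
  buf.reserve((size_t)w * w * w);
  for (int k = 0; k < nz; ++k) {
    const int k0 = std::max(0, k - radius), k1 = std::min(nz - 1, k + radius);
    for (int j = 0; j < ny; ++j) {
      const int j0 = std::max(0, j - radius), j1 = std::min(ny - 1, j + radius);
      for (int i = 0; i < nx; ++i) {
        const int i0 = std::max(0, i - radius), i1 = std::min(nx - 1, i + radius);
        buf.clear();
        for (int kk = k0; kk <= k1; ++kk)
          for (int jj = j0; jj <= j1; ++jj) {
            const R_xlen_t base = lin(i0, jj, kk, nx, ny);
            for (int ii = 0; ii <= i1 - i0; ++ii) buf.push_back(data[base + ii]);
          }
        // neighbourhood truncated at the grid edge: median of what exists
        const size_t n = buf.size();
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        double med = buf[n / 2];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + n / 2);
          med = 0.5 * (lo + med);
        }
        out[lin(i, j, k, nx, ny)] = med;
      }
    }
  }
  return out;
}

// 26-connected component labelling (iterative flood fill).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int ci = (int)(cur % nx);
      int cj = (int)((cur / nx) % ny);
      int ck = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int k2 = ck + dk; if (k2 < 0 || k2 >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int j2 = cj + dj; if (j2 < 0 || j2 >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int i2 = ci + di; if (i2 < 0 || i2 >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t t = lin(i2, j2, k2, nx, ny);
            if (mask[t] && labels[t] == 0) { labels[t] = next; stack.push_back(t); }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

static inline double clamp_eps(double v, int n) {
  // forgive floating round-off at the domain boundary (1e-6 voxel)
  if (v > -1e-6 && v < 0) return 0.0;
  if (v > n - 1 && v < n - 1 + 1e-6) return (double)(n - 1);
  return v;
}

static inline double sample_linear(const double* d, int nx, int ny, int nz,
                                   double x, double y, double z, double fill) {
  x = clamp_eps(x, nx); y = clamp_eps(y, ny); z = clamp_eps(z, nz);
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) --i0;
  if (j0 == ny - 1) --j0;
  if (k0 == nz - 1) --k0;
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1), k1 = std::min(k0 + 1, nz - 1);
  double c000 = d[lin(i0, j0, k0, nx, ny)], c100 = d[lin(i1, j0, k0, nx, ny)];
  double c010 = d[lin(i0, j1, k0, nx, ny)], c110 = d[lin(i1, j1, k0, nx, ny)];
  double c001 = d[lin(i0, j0, k1, nx, ny)], c101 = d[lin(i1, j0, k1, nx, ny)];
  double c011 = d[lin(i0, j1, k1, nx, ny)], c111 = d[lin(i1, j1, k1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Catmull-Rom (Keys, a = -1/2) cubic kernel — near-exact for band-limited
// fields, far less edge-profile smearing than the trilinear tent
static inline double cubw(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.0 + t * t * (-2.5 + 1.5 * t);
  if (t < 2.0) return 2.0 + t * (-4.0 + t * (2.5 - 0.5 * t));
  return 0.0;
}

static inline double sample_cubic(const double* d, int nx, int ny, int nz,
                                  double x, double y, double z, double fill) {
  x = clamp_eps(x, nx); y = clamp_eps(y, ny); z = clamp_eps(z, nz);
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double wx[4], wy[4], wz[4];
  for (int t = 0; t < 4; ++t) {
    wx[t] = cubw(fx - (t - 1));
    wy[t] = cubw(fy - (t - 1));
    wz[t] = cubw(fz - (t - 1));
  }
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    int k = k0 - 1 + c;
    k = k < 0 ? 0 : (k >= nz ? nz - 1 : k);  // clamp at borders
    for (int b = 0; b < 4; ++b) {
      int j = j0 - 1 + b;
      j = j < 0 ? 0 : (j >= ny ? ny - 1 : j);
      double w2 = wz[c] * wy[b];
      for (int a = 0; a < 4; ++a) {
        int i = i0 - 1 + a;
        i = i < 0 ? 0 : (i >= nx ? nx - 1 : i);
        acc += w2 * wx[a] * d[lin(i, j, k, nx, ny)];
      }
    }
  }
  return acc;
}

static inline double sample_nearest(const double* d, int nx, int ny, int nz,
                                    double x, double y, double z, double fill) {
  long i = (long)std::lround(x), j = (long)std::lround(y), k = (long)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
  return d[lin((int)i, (int)j, (int)k, nx, ny)];
}

// Resample `data` (geometry in_*) onto the output grid (out_*), pulling through
// q = A p + b where p is an output-grid physical point.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector data, IntegerVector in_dim,
                           NumericVector in_sp, NumericVector in_or,
                           IntegerVector out_dim, NumericVector out_sp,
                           NumericVector out_or, NumericMatrix A,
                           NumericVector b, int interp, double fill) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* d = data.begin();
  for (int k = 0; k < oz; ++k) {
    double pz = out_or[2] + k * out_sp[2];
    for (int j = 0; j < oy; ++j) {
      double py = out_or[1] + j * out_sp[1];
      for (int i = 0; i < ox; ++i) {
        double px = out_or[0] + i * out_sp[0];
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
        double x = (qx - in_or[0]) / in_sp[0];
        double y = (qy - in_or[1]) / in_sp[1];
        double z = (qz - in_or[2]) / in_sp[2];
        out[lin(i, j, k, ox, oy)] =
          interp == 0 ? sample_linear(d, nx, ny, nz, x, y, z, fill)
          : interp == 1 ? sample_nearest(d, nx, ny, nz, x, y, z, fill)
          : sample_cubic(d, nx, ny, nz, x, y, z, fill);
      }
    }
  }
  return out;
}

// Mean-squared intensity difference between fixed voxels inside bbox
// (0-based, inclusive) and the moving image sampled at A p + b.
// Out-of-domain moving samples take the moving background `fill`.
// [[Rcpp::export]]
double cpp_metric_ssd(NumericVector fixed, IntegerVector f_dim,
                      NumericVector f_sp, NumericVector f_or,
                      NumericVector moving, IntegerVector m_dim,
                      NumericVector m_sp, NumericVector m_or,
                      NumericMatrix A, NumericVector b,
                      IntegerVector lo, IntegerVector hi, double fill,
                      LogicalVector include) {
  const int fnx = f_dim[0], fny = f_dim[1];
  const int mnx = m_dim[0], mny = m_dim[1], mnz = m_dim[2];
  const bool use_mask = include.size() == fixed.size();
  const double* md = moving.begin();
  double acc = 0.0;
  R_xlen_t n = 0;
  for (int k = lo[2]; k <= hi[2]; ++k) {
    double pz = f_or[2] + k * f_sp[2];
    for (int j = lo[1]; j <= hi[1]; ++j) {
      double py = f_or[1] + j * f_sp[1];
      for (int i = lo[0]; i <= hi[0]; ++i) {
        if (use_mask && !include[lin(i, j, k, fnx, fny)]) continue;
        double px = f_or[0] + i * f_sp[0];
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
        double x = (qx - m_or[0]) / m_sp[0];
        double y = (qy - m_or[1]) / m_sp[1];
        double z = (qz - m_or[2]) / m_sp[2];
        double mv = sample_linear(md, mnx, mny, mnz, x, y, z, fill);
        double fv = fixed[lin(i, j, k, fnx, fny)];
        double dd = fv - mv;
        acc += dd * dd;
        ++n;
      }
    }
  }
  return n > 0 ? acc / (double)n : R_PosInf;
}

// Negative mutual information from a joint histogram with linear spreading of
// both intensities across bins (Parzen-style, first-order kernel).
// [[Rcpp::export]]
double cpp_metric_nmi(NumericVector fixed, IntegerVector f_dim,
                      NumericVector f_sp, NumericVector f_or,
                      NumericVector moving, IntegerVector m_dim,
                      NumericVector m_sp, NumericVector m_or,
                      NumericMatrix A, NumericVector b,
                      IntegerVector lo, IntegerVector hi, double fill,
                      int nbins, NumericVector f_range, NumericVector m_range,
                      LogicalVector include) {
  const int fnx = f_dim[0], fny = f_dim[1];
  const int mnx = m_dim[0], mny = m_dim[1], mnz = m_dim[2];
  const bool use_mask = include.size() == fixed.size();
  const double* md = moving.begin();
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  const double fw = (f_range[1] - f_range[0]) / (nbins - 1);
  const double mw = (m_range[1] - m_range[0]) / (nbins - 1);
  double total = 0.0;
  for (int k = lo[2]; k <= hi[2]; ++k) {
    double pz = f_or[2] + k * f_sp[2];
    for (int j = lo[1]; j <= hi[1]; ++j) {
      double py = f_or[1] + j * f_sp[1];
      for (int i = lo[0]; i <= hi[0]; ++i) {
        if (use_mask && !include[lin(i, j, k, fnx, fny)]) continue;
        double px = f_or[0] + i * f_sp[0];
        double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
        double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
        double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
        double x = (qx - m_or[0]) / m_sp[0];
        double y = (qy - m_or[1]) / m_sp[1];
        double z = (qz - m_or[2]) / m_sp[2];
        double mv = sample_linear(md, mnx, mny, mnz, x, y, z, fill);
        double fv = fixed[lin(i, j, k, fnx, fny)];
        double fb = (fv - f_range[0]) / fw;
        double mb = (mv - m_range[0]) / mw;
        fb = std::min(std::max(fb, 0.0), (double)(nbins - 1));
        mb = std::min(std::max(mb, 0.0), (double)(nbins - 1));
        int f0 = std::min((int)std::floor(fb), nbins - 2);
        int m0 = std::min((int)std::floor(mb), nbins - 2);
        double ff = fb - f0, mf = mb - m0;
        joint[(size_t)f0 * nbins + m0] += (1 - ff) * (1 - mf);
        joint[(size_t)f0 * nbins + m0 + 1] += (1 - ff) * mf;
        joint[(size_t)(f0 + 1) * nbins + m0] += ff * (1 - mf);
        joint[(size_t)(f0 + 1) * nbins + m0 + 1] += ff * mf;
        total += 1.0;
      }
    }
  }
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int a = 0; a < nbins; ++a)
    for (int c = 0; c < nbins; ++c) {
      double p = joint[(size_t)a * nbins + c] / total;
      pf[a] += p;
      pm[c] += p;
    }
  double mi = 0.0;
  for (int a = 0; a < nbins; ++a)
    for (int c = 0; c < nbins; ++c) {
      double p = joint[(size_t)a * nbins + c] / total;
      if (p > 1e-12 && pf[a] > 1e-12 && pm[c] > 1e-12)
        mi += p * std::log(p / (pf[a] * pm[c]));
    }
  return -mi;
}

// Separable Gaussian blur, sigma per axis in voxels, kernel truncated at 4 sigma
// and renormalised at the borders.
static void blur_axis(std::vector<double>& src, std::vector<double>& dst,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) { dst = src; return; }
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  for (int t = -r; t <= r; ++t) ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int pos[3] = {i, j, k};
        double acc = 0.0, wsum = 0.0;
        const int c = pos[axis];
        const R_xlen_t base = lin(i, j, k, nx, ny) - (R_xlen_t)c * st;
        const int t0 = std::max(-r, -c), t1 = std::min(r, len - 1 - c);
        for (int t = t0; t <= t1; ++t) {
          double w = ker[t + r];
          acc += w * src[base + (R_xlen_t)(c + t) * st];
          wsum += w;
        }
        dst[lin(i, j, k, nx, ny)] = acc / wsum;
      }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector data, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(data.begin(), data.end()), bvec(data.size());
  blur_axis(a, bvec, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(bvec, a, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(a, bvec, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(data.size());
  std::copy(bvec.begin(), bvec.end(), out.begin());
  return out;
}

// Volume enclosed by the 0.5 iso-surface of a binary field, computed on the
// Kuhn (6-tetrahedra) triangulation of each inter-voxel cell with the field
// zero-padded so the surface is closed. For a binary field all edge crossings
// sit at edge midpoints, so each tetrahedron contributes a fixed fraction of
// its volume by its count of inside vertices: 0 -> 0, 1 -> 1/8, 2 -> 1/2
// (the mid-edge parallelogram bisects any tetrahedron), 3 -> 7/8, 4 -> 1.
// [[Rcpp::export]]
double cpp_mesh_volume(LogicalVector mask, IntegerVector dim, NumericVector sp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // padded grid of size (n+2) per axis, cells between padded voxel centres
  auto val = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return mask[lin(i, j, k, nx, ny)] ? 1 : 0;
  };
  // inside-vertex-count -> fraction of tet volume inside, times tet volume 1/6
  static const double frac[5] = {0.0, 1.0 / 8, 1.0 / 2, 7.0 / 8, 1.0};
  // Kuhn tets as corner indices of the unit cube (bit0=x, bit1=y, bit2=z):
  // each is a monotone path 0 -> 7
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  double acc = 0.0;
  int c[8];
  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        c[0] = val(i, j, k);     c[1] = val(i + 1, j, k);
        c[2] = val(i, j + 1, k); c[3] = val(i + 1, j + 1, k);
        c[4] = val(i, j, k + 1); c[5] = val(i + 1, j, k + 1);
        c[6] = val(i, j + 1, k + 1); c[7] = val(i + 1, j + 1, k + 1);
        int tot = c[0] + c[1] + c[2] + c[3] + c[4] + c[5] + c[6] + c[7];
        if (tot == 0) continue;
        if (tot == 8) { acc += 1.0; continue; }
        for (int t = 0; t < 6; ++t) {
          int nin = c[tets[t][0]] + c[tets[t][1]] + c[tets[t][2]] + c[tets[t][3]];
          acc += frac[nin] / 6.0;
        }
      }
  return acc * sp[0] * sp[1] * sp[2];
}
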