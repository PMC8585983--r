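// Backward-warp resampling (linear or Catmull-Rom cubic) and point-wise
// interpolation of scalar volumes. Indices are voxel units, 0-based.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>

using namespace Rcpp;

namespace {

inline void cubic_w(double t, double w[4]) {
  // Catmull-Rom
  const double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2 * t2 - t);
  w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
  w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

inline int clampi(int x, int lo, int hi) { return x < lo ? lo : (x > hi ? hi : x); }

struct Vol {
  const double *d;
  int n[3];
  inline double at(int i, int j, int k) const {
    return d[(std::size_t)i + (std::size_t)n[0] * ((std::size_t)j + (std::size_t)n[1] * k)];
  }
};

// Interpolate at voxel coordinate x (0-based). Returns value; sets inside
// (sample position within the domain) and valid (full interpolation support,
// i.e. at least one voxel away from every populated boundary).
double interp_one(const Vol &v, const double x[3], bool cubic, bool &inside,
                  bool &valid) {
  inside = true; valid = true;
  for (int a = 0; a < 3; ++a) {
    if (v.n[a] == 1) continue;
    if (x[a] < 0.0 || x[a] > v.n[a] - 1.0) { inside = false; valid = false; return 0.0; }
    if (x[a] < 1.0 || x[a] > v.n[a] - 2.0) valid = false;
  }
  int base[3]; double frac[3];
  for (int a = 0; a < 3; ++a) {
    if (v.n[a] == 1) { base[a] = 0; frac[a] = 0.0; continue; }
    double fl = std::floor(x[a]);
    if (fl > v.n[a] - 2) fl = v.n[a] - 2;  // x exactly at the upper edge
    base[a] = (int)fl;
    frac[a] = x[a] - fl;
  }
  double acc = 0.0;
  if (cubic) {
    double wx[4], wy[4], wz[4];
    int nx, ny, nz;
    double *ws[3] = {wx, wy, wz};
    int *ns[3] = {&nx, &ny, &nz};
    for (int a = 0; a < 3; ++a) {
      if (v.n[a] == 1) { ws[a][0] = 1.0; *ns[a] = 1; }
      else { cubic_w(frac[a], ws[a]); *ns[a] = 4; }
    }
    for (int kk = 0; kk < nz; ++kk) {
      const int k = v.n[2] == 1 ? 0 : clampi(base[2] - 1 + kk, 0, v.n[2] - 1);
      for (int jj = 0; jj < ny; ++jj) {
        const int j = v.n[1] == 1 ? 0 : clampi(base[1] - 1 + jj, 0, v.n[1] - 1);
        double row = 0.0;
        for (int ii = 0; ii < nx; ++ii) {
          const int i = v.n[0] == 1 ? 0 : clampi(base[0] - 1 + ii, 0, v.n[0] - 1);
          row += wx[ii] * v.at(i, j, k);
        }
        acc += wy[jj] * wz[kk] * row;
      }
    }
  } else {
    for (int kk = 0; kk < (v.n[2] == 1 ? 1 : 2); ++kk) {
      const int k = v.n[2] == 1 ? 0 : base[2] + kk;
      const double wk = v.n[2] == 1 ? 1.0 : (kk ? frac[2] : 1.0 - frac[2]);
      for (int jj = 0; jj < (v.n[1] == 1 ? 1 : 2); ++jj) {
        const int j = v.n[1] == 1 ? 0 : base[1] + jj;
        const double wj = v.n[1] == 1 ? 1.0 : (jj ? frac[1] : 1.0 - frac[1]);
        for (int ii = 0; ii < (v.n[0] == 1 ? 1 : 2); ++ii) {
          const int i = v.n[0] == 1 ? 0 : base[0] + ii;
          const double wi = v.n[0] == 1 ? 1.0 : (ii ? frac[0] : 1.0 - frac[0]);
          acc += wi * wj * wk * v.at(i, j, k);
        }
      }
    }
  }
  return acc < 0.0 ? 0.0 : acc;  // photoacoustic amplitudes are non-negative
}

Vol as_vol(const NumericVector &x) {
  Vol v;
  IntegerVector dd = x.attr("dim");
  v.n[0] = dd[0]; v.n[1] = dd[1]; v.n[2] = dd.size() == 3 ? dd[2] : 1;
  v.d = REAL(x);
  return v;
}

}  // namespace

// Backward affine warp: input voxel coordinate = A %*% out + b (all in voxel
// units, 0-based, column-major 3x3 A). Returns list(data, mask).
// [[Rcpp::export(name = "cpp_warp_affine")]]
List cpp_warp_affine(NumericVector data, NumericMatrix A, NumericVector b,
                     bool cubic) {
  Vol v = as_vol(data);
  const std::size_t ntot = (std::size_t)v.n[0] * v.n[1] * v.n[2];
  NumericVector out((R_xlen_t)ntot);
  LogicalVector mask((R_xlen_t)ntot);
  std::size_t q = 0;
  for (int k = 0; k < v.n[2]; ++k)
    for (int j = 0; j < v.n[1]; ++j)
      for (int i = 0; i < v.n[0]; ++i, ++q) {
        const double x[3] = {
            A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + b[0],
            A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + b[1],
            A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + b[2]};
        bool inside, valid;
        out[q] = interp_one(v, x, cubic, inside, valid);
        mask[q] = valid;
      }
  out.attr("dim") = data.attr("dim");
  mask.attr("dim") = data.attr("dim");
  return List::create(_["data"] = out, _["mask"] = mask);
}

// [[Rcpp::export(name = "cpp_interp_points")]]
List cpp_interp_points(NumericVector data, NumericMatrix pts, bool cubic) {
  Vol v = as_vol(data);
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector mask(n);
  for (int r = 0; r < n; ++r) {
    const double x[3] = {pts(r, 0), pts(r, 1), pts(r, 2)};
    bool inside, valid;
    out[r] = interp_one(v, x, cubic, inside, valid);
    mask[r] = valid;
  }
  return List::create(_["data"] = out, _["mask"] = mask);
}
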