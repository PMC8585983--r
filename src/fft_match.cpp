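// Zero-normalized cross-correlation maps for block matching.
//
// The correlation numerator is computed with FFTW (cross-correlation
// theorem) on a zero-padded grid; the per-position window mean/variance of
// the searched region comes from 3-D summed-area tables, so one map costs
// three real FFTs plus O(region) arithmetic regardless of window size.

#include <Rcpp.h>
#include <fftw3.h>
#include <cmath>
#include <map>
#include <array>
#include <vector>

using namespace Rcpp;

namespace {

struct FftPlan {
  std::array<int, 3> dim;   // column-major dims (d0 fastest)
  std::size_t nreal, ncplx;
  double *rbuf;
  fftw_complex *cbuf_a, *cbuf_b;
  fftw_plan fwd, bwd;
};

std::map<std::array<int, 3>, FftPlan> &plan_cache() {
  static std::map<std::array<int, 3>, FftPlan> cache;
  return cache;
}

bool fast_ok(int n) {
  for (int f : {2, 3, 5}) while (n % f == 0) n /= f;
  return n == 1;
}

int fast_size(int n) {
  while (!fast_ok(n)) ++n;
  return n;
}

FftPlan &get_plan(const std::array<int, 3> &dim) {
  auto &cache = plan_cache();
  auto it = cache.find(dim);
  if (it != cache.end()) return it->second;
  FftPlan p;
  p.dim = dim;
  p.nreal = (std::size_t)dim[0] * dim[1] * dim[2];
  p.ncplx = (std::size_t)(dim[0] / 2 + 1) * dim[1] * dim[2];
  p.rbuf = (double *)fftw_malloc(sizeof(double) * p.nreal);
  p.cbuf_a = (fftw_complex *)fftw_malloc(sizeof(fftw_complex) * p.ncplx);
  p.cbuf_b = (fftw_complex *)fftw_malloc(sizeof(fftw_complex) * p.ncplx);
  // FFTW is row-major; R arrays are column-major, so reverse the dims.
  p.fwd = fftw_plan_dft_r2c_3d(dim[2], dim[1], dim[0], p.rbuf, p.cbuf_a,
                               FFTW_ESTIMATE);
  p.bwd = fftw_plan_dft_c2r_3d(dim[2], dim[1], dim[0], p.cbuf_a, p.rbuf,
                               FFTW_ESTIMATE);
  auto res = cache.emplace(dim, p);
  return res.first->second;
}

inline std::size_t idx3(int i, int j, int k, const std::array<int, 3> &d) {
  return (std::size_t)i + (std::size_t)d[0] * ((std::size_t)j + (std::size_t)d[1] * k);
}

// Inclusive 3-D prefix sums with a zero border, dims (d+1).
void prefix_sums(const std::vector<double> &x, const std::array<int, 3> &d,
                 std::vector<double> &cum, bool square) {
  std::array<int, 3> e = {d[0] + 1, d[1] + 1, d[2] + 1};
  cum.assign((std::size_t)e[0] * e[1] * e[2], 0.0);
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        double v = x[idx3(i, j, k, d)];
        if (square) v *= v;
        cum[idx3(i + 1, j + 1, k + 1, e)] =
            v + cum[idx3(i, j + 1, k + 1, e)] + cum[idx3(i + 1, j, k + 1, e)] +
            cum[idx3(i + 1, j + 1, k, e)] - cum[idx3(i, j, k + 1, e)] -
            cum[idx3(i, j + 1, k, e)] - cum[idx3(i + 1, j, k, e)] +
            cum[idx3(i, j, k, e)];
      }
}

inline double box_sum(const std::vector<double> &cum, const std::array<int, 3> &e,
                      int i0, int j0, int k0, int i1, int j1, int k1) {
  // sum over [i0,i1) x [j0,j1) x [k0,k1)
  return cum[idx3(i1, j1, k1, e)] - cum[idx3(i0, j1, k1, e)] -
         cum[idx3(i1, j0, k1, e)] - cum[idx3(i1, j1, k0, e)] +
         cum[idx3(i0, j0, k1, e)] + cum[idx3(i0, j1, k0, e)] +
         cum[idx3(i1, j0, k0, e)] - cum[idx3(i0, j0, k0, e)];
}

// Core: ZNCC of `tmpl` against every fully-overlapping placement in `region`.
// Output dims = region - tmpl + 1. Returns false if the template is
// (numerically) constant.
bool zncc_map_core(const std::vector<double> &tmpl, const std::array<int, 3> &td,
                   const std::vector<double> &region, const std::array<int, 3> &rd,
                   std::vector<double> &out, std::array<int, 3> &od) {
  for (int a = 0; a < 3; ++a) {
    od[a] = rd[a] - td[a] + 1;
    if (od[a] < 1) Rcpp::stop("region smaller than template along axis %d", a + 1);
  }
  const double ntd = (double)td[0] * td[1] * td[2];
  double mean = 0.0, sumsq = 0.0;
  for (double v : tmpl) { mean += v; sumsq += v * v; }
  mean /= ntd;
  double ssT = 0.0;
  std::vector<double> tmpl0(tmpl.size());
  for (std::size_t i = 0; i < tmpl.size(); ++i) {
    tmpl0[i] = tmpl[i] - mean;
    ssT += tmpl0[i] * tmpl0[i];
  }
  if (!(ssT > 1e-12 * (sumsq + 1e-300))) return false;  // constant template

  std::array<int, 3> pd = {fast_size(rd[0]), fast_size(rd[1]), fast_size(rd[2])};
  FftPlan &plan = get_plan(pd);

  // forward FFT of the region
  std::fill(plan.rbuf, plan.rbuf + plan.nreal, 0.0);
  for (int k = 0; k < rd[2]; ++k)
    for (int j = 0; j < rd[1]; ++j)
      for (int i = 0; i < rd[0]; ++i)
        plan.rbuf[idx3(i, j, k, pd)] = region[idx3(i, j, k, rd)];
  fftw_execute_dft_r2c(plan.fwd, plan.rbuf, plan.cbuf_b);

  // forward FFT of the zero-mean template
  std::fill(plan.rbuf, plan.rbuf + plan.nreal, 0.0);
  for (int k = 0; k < td[2]; ++k)
    for (int j = 0; j < td[1]; ++j)
      for (int i = 0; i < td[0]; ++i)
        plan.rbuf[idx3(i, j, k, pd)] = tmpl0[idx3(i, j, k, td)];
  fftw_execute_dft_r2c(plan.fwd, plan.rbuf, plan.cbuf_a);

  // conj(template) * region, then inverse
  for (std::size_t i = 0; i < plan.ncplx; ++i) {
    const double ar = plan.cbuf_a[i][0], ai = plan.cbuf_a[i][1];
    const double br = plan.cbuf_b[i][0], bi = plan.cbuf_b[i][1];
    plan.cbuf_a[i][0] = ar * br + ai * bi;
    plan.cbuf_a[i][1] = ar * bi - ai * br;
  }
  fftw_execute_dft_c2r(plan.bwd, plan.cbuf_a, plan.rbuf);
  const double scale = 1.0 / (double)plan.nreal;

  std::vector<double> cum1, cum2;
  prefix_sums(region, rd, cum1, false);
  prefix_sums(region, rd, cum2, true);
  std::array<int, 3> e = {rd[0] + 1, rd[1] + 1, rd[2] + 1};

  out.assign((std::size_t)od[0] * od[1] * od[2], 0.0);
  for (int k = 0; k < od[2]; ++k)
    for (int j = 0; j < od[1]; ++j)
      for (int i = 0; i < od[0]; ++i) {
        const double raw = plan.rbuf[idx3(i, j, k, pd)] * scale;
        const double s1 = box_sum(cum1, e, i, j, k, i + td[0], j + td[1], k + td[2]);
        const double s2 = box_sum(cum2, e, i, j, k, i + td[0], j + td[1], k + td[2]);
        const double var = s2 - s1 * s1 / ntd;
        double c = 0.0;
        if (var > 1e-12 * (s2 + 1e-300)) {
          c = raw / std::sqrt(ssT * var);
          if (c > 1.0) c = 1.0;
          if (c < -1.0) c = -1.0;
        }
        out[idx3(i, j, k, od)] = c;
      }
  return true;
}

std::array<int, 3> arr_dims(const NumericVector &x) {
  std::array<int, 3> d = {0, 0, 1};
  if (x.hasAttribute("dim")) {
    IntegerVector dd = x.attr("dim");
    if (dd.size() < 2 || dd.size() > 3) Rcpp::stop("expected a 2-D or 3-D array");
    d[0] = dd[0]; d[1] = dd[1]; d[2] = dd.size() == 3 ? dd[2] : 1;
  } else Rcpp::stop("expected an array with a dim attribute");
  return d;
}

}  // namespace

// [[Rcpp::export(name = "cpp_zncc_map")]]
SEXP cpp_zncc_map(NumericVector tmpl, NumericVector region) {
  std::array<int, 3> td = arr_dims(tmpl), rd = arr_dims(region), od;
  std::vector<double> t(tmpl.begin(), tmpl.end());
  std::vector<double> r(region.begin(), region.end());
  std::vector<double> out;
  bool ok = zncc_map_core(t, td, r, rd, out, od);
  if (!ok) return R_NilValue;
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  return res;
}

// Multi-candidate, multi-window matching between two frames.
//
// locs: n x 3 integer matrix of 0-based search-centre voxel indices in `nxt`.
// tlocs: n x 3 integer matrix of template-centre voxel indices in `prev`
//        (equal to locs for incremental tracking; the original reference
//        location when windows come from the reference frame).
// wins: k x 3 integer matrix of odd window extents.
// search: length-3 odd search extents (positions scanned around each loc).
// Returns an n x (k*5) matrix: per window (dx, dy, dz, corr, status) with
// d the displacement of the matched centre relative to loc, and status
// 0 = ok, 1 = degenerate template, 2 = window/search out of bounds.
// Ties in the correlation argmax break by smallest |d|^2, then by
// lexicographic (dx, dy, dz). If subvoxel is true, a three-point parabolic
// refinement is applied per axis to the winning integer displacement.
// [[Rcpp::export(name = "cpp_match_windows")]]
NumericMatrix cpp_match_windows(NumericVector prev, NumericVector nxt,
                                IntegerMatrix locs, IntegerMatrix tlocs,
                                IntegerMatrix wins,
                                IntegerVector search, bool subvoxel) {
  std::array<int, 3> nd = arr_dims(prev);
  std::array<int, 3> nd2 = arr_dims(nxt);
  for (int a = 0; a < 3; ++a)
    if (nd[a] != nd2[a]) Rcpp::stop("frames differ in shape");
  const int n = locs.nrow(), nw = wins.nrow();
  if (search.size() != 3) Rcpp::stop("search must have length 3");
  NumericMatrix res(n, nw * 5);

  const double *pv = REAL(prev);
  const double *nv = REAL(nxt);

  if (tlocs.nrow() != n) Rcpp::stop("locs/tlocs row mismatch");

  for (int c = 0; c < n; ++c) {
    int loc[3] = {locs(c, 0), locs(c, 1), locs(c, 2)};
    int tlc[3] = {tlocs(c, 0), tlocs(c, 1), tlocs(c, 2)};
    for (int w = 0; w < nw; ++w) {
      const int col0 = w * 5;
      int h[3], dlo[3], dhi[3];
      bool bad = false;
      for (int a = 0; a < 3; ++a) {
        h[a] = (wins(w, a) - 1) / 2;
        const int sh = (search[a] - 1) / 2;
        if (tlc[a] - h[a] < 0 || tlc[a] + h[a] > nd[a] - 1) bad = true;  // template
        dlo[a] = std::max(-sh, h[a] - loc[a]);
        dhi[a] = std::min(sh, nd[a] - 1 - h[a] - loc[a]);
        if (dlo[a] > dhi[a]) bad = true;
      }
      if (bad) { res(c, col0 + 4) = 2.0; continue; }

      std::array<int, 3> td, rd;
      int rlo[3];
      for (int a = 0; a < 3; ++a) {
        td[a] = wins(w, a);
        rlo[a] = loc[a] + dlo[a] - h[a];
        rd[a] = (dhi[a] - dlo[a]) + wins(w, a);
      }
      std::vector<double> tmpl((std::size_t)td[0] * td[1] * td[2]);
      for (int k = 0; k < td[2]; ++k)
        for (int j = 0; j < td[1]; ++j)
          for (int i = 0; i < td[0]; ++i)
            tmpl[idx3(i, j, k, td)] =
                pv[idx3(tlc[0] - h[0] + i, tlc[1] - h[1] + j, tlc[2] - h[2] + k, nd)];
      std::vector<double> region((std::size_t)rd[0] * rd[1] * rd[2]);
      for (int k = 0; k < rd[2]; ++k)
        for (int j = 0; j < rd[1]; ++j)
          for (int i = 0; i < rd[0]; ++i)
            region[idx3(i, j, k, rd)] =
                nv[idx3(rlo[0] + i, rlo[1] + j, rlo[2] + k, nd)];

      std::vector<double> zmap;
      std::array<int, 3> od;
      if (!zncc_map_core(tmpl, td, region, rd, zmap, od)) {
        res(c, col0 + 4) = 1.0;  // degenerate template
        continue;
      }
      // a constant search region carries no texture to lock onto
      double rmin = region[0], rmax = region[0];
      for (double v : region) { rmin = std::min(rmin, v); rmax = std::max(rmax, v); }
      if (rmax - rmin <= 1e-12 * (std::fabs(rmax) + 1e-300)) {
        res(c, col0 + 4) = 1.0;
        continue;
      }
      // offset o in zmap corresponds to displacement d = dlo + o; values
      // within tie_eps count as ties (FFT round-off would otherwise break
      // exact symmetry), resolved by smallest |d|, then lexicographically
      const double tie_eps = 1e-9;
      double best = -2.0;
      long best_mag = 0;
      int bd[3] = {0, 0, 0}, bo[3] = {0, 0, 0};
      for (int k = 0; k < od[2]; ++k)
        for (int j = 0; j < od[1]; ++j)
          for (int i = 0; i < od[0]; ++i) {
            const double v = zmap[idx3(i, j, k, od)];
            const int d0 = dlo[0] + i, d1 = dlo[1] + j, d2 = dlo[2] + k;
            const long mag = (long)d0 * d0 + (long)d1 * d1 + (long)d2 * d2;
            bool take = false;
            if (v > best + tie_eps) take = true;
            else if (v > best - tie_eps) {
              if (mag < best_mag) take = true;
              else if (mag == best_mag) {
                if (d0 < bd[0] || (d0 == bd[0] && (d1 < bd[1] ||
                    (d1 == bd[1] && d2 < bd[2])))) take = true;
              }
            }
            if (take) {
              best = std::max(best, v); best_mag = mag;
              bd[0] = d0; bd[1] = d1; bd[2] = d2;
              bo[0] = i; bo[1] = j; bo[2] = k;
            }
          }
      double fd[3] = {(double)bd[0], (double)bd[1], (double)bd[2]};
      if (subvoxel) {
        for (int a = 0; a < 3; ++a) {
          if (od[a] < 3 || bo[a] == 0 || bo[a] == od[a] - 1) continue;
          int om[3] = {bo[0], bo[1], bo[2]}, op[3] = {bo[0], bo[1], bo[2]};
          om[a] -= 1; op[a] += 1;
          const double cm = zmap[idx3(om[0], om[1], om[2], od)];
          const double c0 = best;
          const double cp = zmap[idx3(op[0], op[1], op[2], od)];
          const double den = cm - 2.0 * c0 + cp;
          if (den < -1e-12) {
            double delta = 0.5 * (cm - cp) / den;
            if (delta > 0.5) delta = 0.5;
            if (delta < -0.5) delta = -0.5;
            fd[a] += delta;
          }
        }
      }
      res(c, col0 + 0) = fd[0];
      res(c, col0 + 1) = fd[1];
      res(c, col0 + 2) = fd[2];
      res(c, col0 + 3) = best;
      res(c, col0 + 4) = 0.0;
    }
  }
  return res;
}
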