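// Per-voxel neighbour-contrast map: max over the full 8- (2-D) or 26- (3-D)
// neighbourhood of (I_p - I_n) / max(I_n, eps_floor).

#include <Rcpp.h>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export(name = "cpp_contrast_max")]]
NumericVector cpp_contrast_max(NumericVector data, double eps_floor) {
  IntegerVector dd = data.attr("dim");
  const int n0 = dd[0], n1 = dd[1], n2 = dd.size() == 3 ? dd[2] : 1;
  const double *x = REAL(data);
  NumericVector out((R_xlen_t)n0 * n1 * n2);
  double *o = REAL(out);
  auto at = [&](int i, int j, int k) {
    return x[(std::size_t)i + (std::size_t)n0 * ((std::size_t)j + (std::size_t)n1 * k)];
  };
  std::size_t q = 0;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i, ++q) {
        const double ip = at(i, j, k);
        double best = R_NegInf;
        for (int dk = (n2 == 1 ? 0 : -1); dk <= (n2 == 1 ? 0 : 1); ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n0 || jj < 0 || jj >= n1 || kk < 0 || kk >= n2)
                continue;
              const double in = at(ii, jj, kk);
              const double c = (ip - in) / std::max(in, eps_floor);
              if (c > best) best = c;
            }
        o[q] = best;
      }
  out.attr("dim") = data.attr("dim");
  return out;
}
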