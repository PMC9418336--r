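// Circular-kernel focal median. Kernel membership: pixel centres within
// `radius_px` of the centre pixel (centre included). Edges use the
// truncated kernel; NA/NaN neighbours are skipped. Median convention:
// mean of the two middle order statistics for even counts.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix sf_focal_median(NumericMatrix m, double radius_px) {
  int nr = m.nrow(), nc = m.ncol();
  int r = (int)std::floor(radius_px);
  std::vector<int> dro, dco;
  double r2 = radius_px * radius_px;
  for (int dr = -r; dr <= r; ++dr)
    for (int dc = -r; dc <= r; ++dc)
      if ((double)dr * dr + (double)dc * dc <= r2) {
        dro.push_back(dr);
        dco.push_back(dc);
      }
  int nk = (int)dro.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(nk);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int t = 0; t < nk; ++t) {
        int ii = i + dro[t], jj = j + dco[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = m(ii, jj);
        if (!ISNAN(v)) buf.push_back(v);
      }
      int n = (int)buf.size();
      if (n == 0) {
        out(i, j) = NA_REAL;
      } else {
        int h = n / 2;
        std::nth_element(buf.begin(), buf.begin() + h, buf.end());
        double med = buf[h];
        if (n % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + h);
          med = 0.5 * (med + lo);
        }
        out(i, j) = med;
      }
    }
  }
  return out;
}
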