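#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Poisson recruitment with a truncated, asymmetric negative-exponential
// dispersal kernel. For each parent k the total propagule count is drawn as
// Poisson(lambda0[k]); each propagule is then placed by sampling a
// destination voxel with probability proportional to
//   S_B(v) * exp(-D_K * d(parent, v)) * (D_KAs if dz < 0 else 1)
// over the neighborhood where the kernel exceeds `cut` times its peak
// (equivalent, by Poisson thinning, to independent Poisson counts per
// voxel). Destination admissibility in light is checked by the caller;
// propagules landing outside the plot or on zero substrate are lost here.
//
// Voxel iteration order is fixed (dx outer, then dy, then dz) and mirrored
// by the brute-force oracle used in the tests; RNG draws come from R's
// stream (one rpois per parent, then one unif per propagule).
// [[Rcpp::export]]
List recruit_kernel(IntegerVector px, IntegerVector py, IntegerVector pz,
                    NumericVector lambda0, NumericVector dk,
                    NumericVector dkas, NumericVector sb,
                    IntegerVector dims, double cut) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int npar = px.size();
  const double logcut = -std::log(cut);
  std::vector<int> rx, ry, rz, rparent;
  std::vector<double> w;
  std::vector<int> vx, vy, vz;

  for (int k = 0; k < npar; ++k) {
    if (lambda0[k] <= 0.0) continue;
    int n = (int) R::rpois(lambda0[k]);
    if (n < 1) continue;
    const double dkk = dk[k];
    const double asym = dkas[k];
    const int R = (int) std::ceil(logcut / dkk);
    const double maxd2 = (logcut / dkk) * (logcut / dkk);
    w.clear(); vx.clear(); vy.clear(); vz.clear();
    double wsum = 0.0;
    for (int dx = -R; dx <= R; ++dx) {
      const int x = px[k] + dx;
      if (x < 0 || x >= nx) continue;
      for (int dy = -R; dy <= R; ++dy) {
        const int y = py[k] + dy;
        if (y < 0 || y >= ny) continue;
        const int d2xy = dx * dx + dy * dy;
        if (d2xy > maxd2) continue;
        for (int dz = -R; dz <= R; ++dz) {
          const int z = pz[k] + dz;
          if (z < 0 || z >= nz) continue;
          const double d2 = d2xy + dz * dz;
          if (d2 > maxd2) continue;
          const double s = sb[x + (size_t) nx * (y + (size_t) ny * z)];
          if (s <= 0.0) continue;
          double wk = s * std::exp(-dkk * std::sqrt(d2));
          if (dz < 0) wk *= asym;
          w.push_back(wk);
          vx.push_back(x); vy.push_back(y); vz.push_back(z);
          wsum += wk;
        }
      }
    }
    if (wsum <= 0.0) continue;  // no reachable substrate: propagules lost
    for (int j = 0; j < n; ++j) {
      double u = R::unif_rand() * wsum;
      double acc = 0.0;
      int pick = (int) w.size() - 1;
      for (size_t m = 0; m < w.size(); ++m) {
        acc += w[m];
        if (u <= acc) { pick = (int) m; break; }
      }
      rx.push_back(vx[pick]); ry.push_back(vy[pick]); rz.push_back(vz[pick]);
      rparent.push_back(k + 1);
    }
  }
  return List::create(_["x"] = wrap(rx), _["y"] = wrap(ry),
                      _["z"] = wrap(rz), _["parent"] = wrap(rparent));
}
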