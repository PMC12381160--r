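#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted atom-density representation of a single snapshot.
//
// For every heavy (non-hydrogen) central atom i the per-atom vector is
//   [ A1 (7) | A2: 7 channels x nbin | A3 cos: 7 x nbin | A3 sin: 7 x nbin ]
// with
//   A2(i)^w(r)      = sum_{j != i} w_ij G_ij(r)
//   A3(i)^{w,phi}(r) = sum_{j != k, both != i} w_ij w_ik w_jk G_ij(r) phi(theta_ijk)
// where G_ij is a normal density centred at d_ij (width sigma), theta_ijk is
// the angle at vertex i between i->j and i->k, and the sums run over
// neighbours within the cutoff. The double sum is factorised as
//   sum_j w_ij G_ij(r) * ( sum_{k != j} w_ik w_jk phi(theta_ijk) )
// which keeps the kernel O(m^2) per centre instead of O(m^2 * nbin).
//
// omega: list of 7 N x N weight matrices in canonical channel order.
// [[Rcpp::export]]
NumericMatrix snapshotRepCpp(NumericMatrix coords, List omega,
                             NumericMatrix a1, LogicalVector heavy,
                             NumericVector centers, double sigma,
                             double cutoff, bool includeH) {
  const int n = coords.nrow();
  const int nbin = centers.size();
  const int nch = omega.size();
  const int rowlen = a1.ncol() + nch * nbin + 2 * nch * nbin;
  const double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  std::vector<NumericMatrix> W;
  for (int c = 0; c < nch; ++c) W.push_back(as<NumericMatrix>(omega[c]));

  int nheavy = 0;
  for (int i = 0; i < n; ++i) if (heavy[i]) ++nheavy;
  NumericMatrix out(nheavy, rowlen);

  std::vector<double> g;       // Gaussian profile of one neighbour
  std::vector<int> nbr;        // neighbour indices of the current centre
  std::vector<double> ux, uy, uz, dd;

  int row = -1;
  for (int i = 0; i < n; ++i) {
    if (!heavy[i]) continue;
    ++row;
    for (int f = 0; f < a1.ncol(); ++f) out(row, f) = a1(i, f);

    nbr.clear(); ux.clear(); uy.clear(); uz.clear(); dd.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (!includeH && !heavy[j]) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > cutoff || d <= 0.0) continue;
      nbr.push_back(j);
      ux.push_back(dx / d); uy.push_back(dy / d); uz.push_back(dz / d);
      dd.push_back(d);
    }
    const int m = (int)nbr.size();
    const int offA2 = a1.ncol();
    const int offCos = offA2 + nch * nbin;
    const int offSin = offCos + nch * nbin;

    g.assign(nbin, 0.0);
    std::vector<double> coefC(nch), coefS(nch);
    for (int a = 0; a < m; ++a) {
      const int j = nbr[a];
      const double d = dd[a];
      for (int b = 0; b < nbin; ++b) {
        double x = d - centers[b];
        g[b] = norm * std::exp(-x * x * inv2s2);
      }
      // three-body coefficients: sum over the second neighbour k
      for (int c = 0; c < nch; ++c) { coefC[c] = 0.0; coefS[c] = 0.0; }
      for (int bkt = 0; bkt < m; ++bkt) {
        if (bkt == a) continue;
        const int k = nbr[bkt];
        double ct = ux[a] * ux[bkt] + uy[a] * uy[bkt] + uz[a] * uz[bkt];
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
        double st = std::sqrt(1.0 - ct * ct);
        for (int c = 0; c < nch; ++c) {
          double wikwjk = W[c](i, k) * W[c](j, k);
          coefC[c] += wikwjk * ct;
          coefS[c] += wikwjk * st;
        }
      }
      for (int c = 0; c < nch; ++c) {
        const double wij = W[c](i, j);
        const double wc = wij * coefC[c], ws = wij * coefS[c];
        for (int b = 0; b < nbin; ++b) {
          out(row, offA2 + c * nbin + b) += wij * g[b];
          out(row, offCos + c * nbin + b) += wc * g[b];
          out(row, offSin + c * nbin + b) += ws * g[b];
        }
      }
    }
  }
  return out;
}
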