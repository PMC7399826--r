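#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-spiral point set on each expanded atomic sphere. Coordinates and
// radii in nm; returns per-atom accessible areas (nm^2).
//
// A surface point of atom i is buried when it falls strictly inside the
// expanded sphere of any other atom j. Exactly coincident atoms of equal
// radius are tie-broken by index (the later duplicate is buried by the
// earlier one) so duplicated atoms do not double-count area.
// [[Rcpp::export]]
NumericVector sasa_atom_areas_cpp(NumericMatrix coords, NumericVector radii,
                                  double probe, int npoints) {
  const int n = coords.nrow();
  const double golden = M_PI * (3.0 - std::sqrt(5.0));

  // unit-sphere point set
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = k * golden;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }

  NumericVector area(n);
  const double tol = 1e-12;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);

  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    // neighbour list: atoms whose expanded sphere can occlude sphere i
    std::vector<int> nb;
    const double cut = Ri + rmax + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double Rj = radii[j] + probe;
      double lim = Ri + Rj;
      if (d2 < lim * lim && d2 < cut * cut) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < npoints; ++k) {
      const double sx = xi + Ri * px[k], sy = yi + Ri * py[k],
                   sz = zi + Ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double Rj = radii[j] + probe;
        double dx = sx - coords(j, 0), dy = sy - coords(j, 1),
               dz = sz - coords(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < Rj * Rj - tol) { buried = true; break; }
        // duplicate-atom tie-break
        if (j < i && std::fabs(Rj - Ri) < tol) {
          double cx = coords(j, 0) - xi, cy = coords(j, 1) - yi,
                 cz = coords(j, 2) - zi;
          if (cx * cx + cy * cy + cz * cz < tol) { buried = true; break; }
        }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * exposed / npoints;
  }
  return area;
}
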