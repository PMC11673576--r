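#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum-image pair-distance histogram in an orthorhombic periodic box.
// pa, pb: N x 3 position matrices (nm). When `same` is true pa and pb hold
// the same particles and each unordered pair is counted once (self pairs
// excluded); otherwise every cross pair (a, b) is counted once.
// [[Rcpp::export]]
NumericVector pair_histogram(NumericMatrix pa, NumericMatrix pb,
                             NumericVector box, double bin_width,
                             int nbins, bool same) {
  NumericVector counts(nbins);
  const int na = pa.nrow(), nb = pb.nrow();
  const double lx = box[0], ly = box[1], lz = box[2];
  const double rmax = nbins * bin_width;
  const double rmax2 = rmax * rmax;
  for (int i = 0; i < na; ++i) {
    const double xi = pa(i, 0), yi = pa(i, 1), zi = pa(i, 2);
    const int j0 = same ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      double dx = xi - pb(j, 0);
      double dy = yi - pb(j, 1);
      double dz = zi - pb(j, 2);
      dx -= lx * std::nearbyint(dx / lx);
      dy -= ly * std::nearbyint(dy / ly);
      dz -= lz * std::nearbyint(dz / lz);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rmax2) {
        const int k = static_cast<int>(std::sqrt(r2) / bin_width);
        if (k < nbins) counts[k] += 1.0;
      }
    }
  }
  return counts;
}
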