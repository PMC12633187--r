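#include <Rcpp.h>
using namespace Rcpp;

// Minimal vdW-corrected distance ("clearance") from each candidate plane
// point to the nearest atom sphere. Hot kernel of the pore profiler.
// [[Rcpp::export(name = ".clearance_cpp")]]
NumericVector clearance_cpp(NumericVector gx, NumericVector gy, double z,
                            NumericVector ax, NumericVector ay,
                            NumericVector az, NumericVector vdw) {
  const int G = gx.size(), A = ax.size();
  NumericVector out(G);
  std::vector<double> dz2(A);
  for (int i = 0; i < A; ++i) {
    const double dz = z - az[i];
    dz2[i] = dz * dz;
  }
  for (int g = 0; g < G; ++g) {
    double best = R_PosInf;
    const double x = gx[g], y = gy[g];
    for (int i = 0; i < A; ++i) {
      const double dx = x - ax[i], dy = y - ay[i];
      const double d = std::sqrt(dx * dx + dy * dy + dz2[i]) - vdw[i];
      if (d < best) best = d;
    }
    out[g] = best;
  }
  return out;
}
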