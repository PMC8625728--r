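#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics walk of N independent point particles released at
// (0, 0, d), with an absorbing sphere of radius Rr at the origin.
// Each step adds an isotropic Gaussian displacement of per-axis standard
// deviation sigma; a particle is absorbed when its end-of-step radius is
// <= Rr (no bridge correction, so the first-passage CDF is slightly
// underestimated; the bias shrinks with the step size). Uses R's RNG so
// results are reproducible under set.seed(). Returns the first-passage
// step index (NA when never absorbed) and the final positions.
// [[Rcpp::export]]
List brownian_absorbing_sphere(int N, double sigma, double d, double Rr,
                               int n_steps) {
  IntegerVector fp_step(N, NA_INTEGER);
  NumericVector xs(N), ys(N), zs(N, d);
  std::vector<bool> alive(N, true);
  int n_alive = N;
  const double Rr2 = Rr * Rr;
  for (int s = 1; s <= n_steps && n_alive > 0; ++s) {
    for (int i = 0; i < N; ++i) {
      if (!alive[i]) continue;
      xs[i] += R::norm_rand() * sigma;
      ys[i] += R::norm_rand() * sigma;
      zs[i] += R::norm_rand() * sigma;
      if (xs[i] * xs[i] + ys[i] * ys[i] + zs[i] * zs[i] <= Rr2) {
        alive[i] = false;
        fp_step[i] = s;
        --n_alive;
      }
    }
  }
  return List::create(_["fp_step"] = fp_step,
                      _["x"] = xs, _["y"] = ys, _["z"] = zs);
}
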