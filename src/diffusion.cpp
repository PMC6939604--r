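#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of a two-boundary Wiener diffusion.
// Evidence starts at a/2 (unbiased), steps by v*dt + s*sqrt(dt)*eps until it
// crosses 0 or a. Uses R's RNG, so results are reproducible via set.seed().
// max_steps guards against (practically impossible) non-absorption.
// [[Rcpp::export(name = ".euler_diffusion")]]
DataFrame euler_diffusion(int n_trials, double v, double a, double ter,
                          double s, double dt, int max_steps = 4000000) {
  if (n_trials < 1) stop("n_trials must be >= 1");
  if (dt <= 0.0 || dt > 0.005) stop("dt must lie in (0, 0.005]");
  if (a <= 0.0) stop("boundary separation must be positive");
  if (s <= 0.0) stop("scaling constant must be positive");

  IntegerVector boundary(n_trials);   // 1 = upper, 0 = lower
  NumericVector decision_time(n_trials);
  const double drift = v * dt;
  const double sigma = s * std::sqrt(dt);
  // Broadie-Glasserman-Kou continuity correction: the discretised process
  // overshoots a continuously-monitored barrier by E[overshoot] =
  // zeta(1/2)/sqrt(2*pi) * sigma ~= 0.5826*sigma per crossing; shifting
  // both absorbing thresholds inward by that amount removes the O(sqrt(dt))
  // first-passage bias, leaving O(dt).
  const double shift = 0.5826 * sigma;
  const double hi = a - shift, lo = shift;
  if (hi <= lo) stop("dt too coarse for this boundary separation");

  for (int i = 0; i < n_trials; ++i) {
    double x = a / 2.0;
    int step = 0;
    while (step < max_steps) {
      x += drift + sigma * norm_rand();
      ++step;
      if (x >= hi) { boundary[i] = 1; break; }
      if (x <= lo) { boundary[i] = 0; break; }
    }
    if (step >= max_steps) stop("diffusion trial failed to absorb");
    decision_time[i] = step * dt;
  }

  return DataFrame::create(
      _["boundary"] = boundary,
      _["decision_time"] = decision_time,
      _["total_rt"] = decision_time + ter);
}
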