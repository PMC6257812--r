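#include <Rcpp.h>
using namespace Rcpp;

// Integrate a reflected random walk on [0, 255]. Reflection is applied
// iteratively after each increment (I = -I below 0, I = 510 - I above 255)
// until the value lands in range; the order of reflections matters, so this
// cannot be folded in vectorized R without changing the path.
// [[Rcpp::export]]
NumericVector cpp_reflect_walk(NumericVector increments, double init) {
  R_xlen_t n = increments.size();
  NumericVector out(n + 1);
  double x = init;
  out[0] = x;
  for (R_xlen_t j = 0; j < n; ++j) {
    x += increments[j];
    while (x < 0.0 || x > 255.0) {
      if (x < 0.0) x = -x;
      if (x > 255.0) x = 510.0 - x;
    }
    out[j + 1] = x;
  }
  return out;
}

// Grid sums for the gain tracker's step likelihood: for each grid gain g,
// returns sum_j exp(b * g * x[j] + c * g^2 * x[j]^2).
// [[Rcpp::export]]
NumericVector cpp_exp_quad_rowsums(NumericVector grid, NumericVector x,
                                   double b, double c) {
  R_xlen_t G = grid.size(), n = x.size();
  NumericVector out(G);
  for (R_xlen_t i = 0; i < G; ++i) {
    double g = grid[i], g2 = g * g, acc = 0.0;
    for (R_xlen_t j = 0; j < n; ++j) {
      double xj = x[j];
      acc += std::exp(b * g * xj + c * g2 * xj * xj);
    }
    out[i] = acc;
  }
  return out;
}

// Poisson thinning of turn decisions for a population of independent larvae.
// p: per-frame turn probability (shared across larvae); after a turn the
// larva is out of the run for `refractory` frames. Returns, per larva, the
// 1-based frame indices at which turns occurred. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List cpp_sim_turn_frames(NumericVector p, int n_larvae, int refractory) {
  R_xlen_t n_frames = p.size();
  List out(n_larvae);
  std::vector<int> turns;
  for (int l = 0; l < n_larvae; ++l) {
    turns.clear();
    R_xlen_t f = 0;
    while (f < n_frames) {
      if (unif_rand() < p[f]) {
        turns.push_back((int)(f + 1));
        f += refractory + 1;
      } else {
        ++f;
      }
    }
    out[l] = IntegerVector(turns.begin(), turns.end());
  }
  return out;
}
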