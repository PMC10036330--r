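#include <Rcpp.h>
using namespace Rcpp;

// Ranks (1-based, ascending) of a Bernoulli(p) subset of 1..total, generated
// by geometric gaps between successes (sampled exactly by inversion from
// uniforms: gap = 1 + floor(log U / log(1 - p))). Exact and O(total * p).
// [[Rcpp::export]]
NumericVector bernoulli_ranks_cpp(double total, double p) {
  std::vector<double> out;
  out.reserve(static_cast<size_t>(total * p * 1.05) + 16);
  const double denom = log1p(-p);
  double pos = 0.0;
  while (true) {
    double u = unif_rand();
    if (u <= 0.0) continue;  // guard against a zero uniform
    pos += 1.0 + std::floor(std::log(u) / denom);
    if (pos > total || !R_FINITE(pos)) break;
    out.push_back(pos);
  }
  return wrap(out);
}

static inline double c2(double v) { return v * (v - 1.0) / 2.0; }
static inline double c3(double v) { return v * (v - 1.0) * (v - 2.0) / 6.0; }

// Per-node incidence counts of a sorted colex rank vector of pairs.
// rank0 = C(x2, 2) + x1 with 0-based nodes x1 < x2.
// [[Rcpp::export]]
IntegerVector pair_incidence_counts_cpp(NumericVector ranks, int n) {
  IntegerVector k(n);
  double x2 = 1.0;
  for (R_xlen_t i = 0; i < ranks.size(); ++i) {
    double r0 = ranks[i] - 1.0;
    while (x2 + 1.0 <= n - 1.0 && c2(x2 + 1.0) <= r0) x2 += 1.0;
    double x1 = r0 - c2(x2);
    ++k[static_cast<int>(x1)];
    ++k[static_cast<int>(x2)];
  }
  return k;
}

// Per-node incidence counts of a sorted colex rank vector of triples.
// rank0 = C(x3, 3) + C(x2, 2) + x1 with 0-based nodes x1 < x2 < x3.
// [[Rcpp::export]]
IntegerVector triple_incidence_counts_cpp(NumericVector ranks, int n) {
  IntegerVector k(n);
  double x3 = 2.0;
  for (R_xlen_t i = 0; i < ranks.size(); ++i) {
    double r0 = ranks[i] - 1.0;
    while (x3 + 1.0 <= n - 1.0 && c3(x3 + 1.0) <= r0) x3 += 1.0;
    double r1 = r0 - c3(x3);
    double x2 = std::floor((1.0 + std::sqrt(8.0 * r1 + 1.0)) / 2.0);
    while (c2(x2) > r1) x2 -= 1.0;
    while (c2(x2 + 1.0) <= r1) x2 += 1.0;
    double x1 = r1 - c2(x2);
    ++k[static_cast<int>(x1)];
    ++k[static_cast<int>(x2)];
    ++k[static_cast<int>(x3)];
  }
  return k;
}
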