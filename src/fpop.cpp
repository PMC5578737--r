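#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Penalized least-squares segmentation (optimal partitioning) for
// piecewise-constant mean with squared-error cost, solved exactly by
// functional pruning (FPOP). Equivalent to PELT / exhaustive dynamic
// programming for the same penalty, but near-linear even when change
// points are sparse, where inequality-based pruning degenerates to O(n^2).
//
// F(t) = min_tau F(tau) + C(tau, t) + beta, F(0) = -beta, with
// C(i, j) = sum_{k in (i, j]} (x_k - mu)^2 minimized over mu. The
// functional cost F_t(mu) is piecewise quadratic in the candidate segment
// mean mu; each piece belongs to a candidate start tau and its quadratic
// is reconstructed from cumulative sums:
//   q_tau(mu) = A mu^2 - 2 B mu + C,
//   A = t - tau, B = s[t] - s[tau], C = F(tau) + beta + ss[t] - ss[tau].
//
// Returns the 1-based indices of the last sample of every segment except
// the final one (empty if the optimum is a single segment).
// [[Rcpp::export(name = ".fpop_mean")]]
IntegerVector fpop_mean(NumericVector x, double beta) {
  const R_xlen_t n = x.size();
  if (n < 1) return IntegerVector(0);

  std::vector<double> s(n + 1, 0.0), ss(n + 1, 0.0);
  double lo_mu = x[0], hi_mu = x[0];
  for (R_xlen_t i = 0; i < n; ++i) {
    s[i + 1] = s[i] + x[i];
    ss[i + 1] = ss[i] + x[i] * x[i];
    if (x[i] < lo_mu) lo_mu = x[i];
    if (x[i] > hi_mu) hi_mu = x[i];
  }
  lo_mu -= 1.0;
  hi_mu += 1.0;  // optimal segment means always lie within the data range

  std::vector<double> F(n + 1);
  std::vector<R_xlen_t> last_cp(n + 1, 0);
  F[0] = -beta;

  struct Piece { double lo, hi; R_xlen_t tau; };
  std::vector<Piece> pieces, next;
  pieces.push_back({lo_mu, hi_mu, 0});

  for (R_xlen_t t = 1; t <= n; ++t) {
    // global minimum of the functional cost at time t
    double best = R_PosInf;
    R_xlen_t best_tau = 0;
    for (const Piece &p : pieces) {
      const double A = (double)(t - p.tau);
      const double B = s[t] - s[p.tau];
      const double C = F[p.tau] + beta + ss[t] - ss[p.tau];
      double mu = B / A;
      if (mu < p.lo) mu = p.lo; else if (mu > p.hi) mu = p.hi;
      const double v = (A * mu - 2.0 * B) * mu + C;
      if (v < best) { best = v; best_tau = p.tau; }
    }
    F[t] = best;
    last_cp[t] = best_tau;
    if (t == n) break;

    // new function: min(old pieces, constant F[t] + beta belonging to tau = t)
    const double y = best + beta;
    next.clear();
    auto push_t = [&](double lo, double hi) {
      if (hi <= lo) return;
      if (!next.empty() && next.back().tau == t)
        next.back().hi = hi;
      else
        next.push_back({lo, hi, t});
    };
    for (const Piece &p : pieces) {
      const double A = (double)(t - p.tau);
      const double B = s[t] - s[p.tau];
      const double C = F[p.tau] + beta + ss[t] - ss[p.tau];
      const double disc = B * B - A * (C - y);
      if (disc <= 0) {            // whole piece at/above the new constant
        push_t(p.lo, p.hi);
        continue;
      }
      const double sq = std::sqrt(disc);
      double r1 = (B - sq) / A, r2 = (B + sq) / A;
      const double keep_lo = r1 > p.lo ? r1 : p.lo;
      const double keep_hi = r2 < p.hi ? r2 : p.hi;
      if (keep_lo >= keep_hi) {
        push_t(p.lo, p.hi);
        continue;
      }
      push_t(p.lo, keep_lo);
      next.push_back({keep_lo, keep_hi, p.tau});
      push_t(keep_hi, p.hi);
    }
    pieces.swap(next);
  }

  std::vector<R_xlen_t> cps;
  R_xlen_t t = n;
  while (last_cp[t] > 0) {
    cps.push_back(last_cp[t]);
    t = last_cp[t];
  }
  IntegerVector out(cps.size());
  for (size_t i = 0; i < cps.size(); ++i)
    out[i] = (int)cps[cps.size() - 1 - i];
  return out;
}
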