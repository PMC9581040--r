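#include <Rcpp.h>
using namespace Rcpp;

// GEV CDF, xi > 0: F(t) = exp(-[1 + xi (t - mu)/sigma]^(-1/xi)), 0 below
// the support endpoint mu - sigma/xi.
static inline double gev_cdf(double t, double mu, double sigma, double xi) {
  double z = 1.0 + xi * (t - mu) / sigma;
  if (z <= 0.0) return 0.0;
  return std::exp(-std::pow(z, -1.0 / xi));
}

static inline double hazard(double t, double dT, double mu, double sigma,
                            double xi, double guard) {
  double f0 = gev_cdf(t, mu, sigma, xi);
  double surv = 1.0 - f0;
  if (surv < guard) return 1.0;   // tail guard: transition certain
  double f1 = gev_cdf(t + dT, mu, sigma, xi);
  double p = (f1 - f0) / surv;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// One discrete time step of the agent-based population.
//
// Cells are processed in stable index order. For every cell one uniform u1
// is drawn; arrested cells ignore it and only age. A non-arrested cell with
// u1 < hazard(t) attempts a transition, for which a second uniform u2 is
// always drawn (even when the effective blocking probability is 0, so the
// random stream is identical with and without the blocking machinery). If
// u2 falls below the effective blocking probability of the cell's phase the
// transition is blocked and the cell ages in place; otherwise the cell
// moves to the next phase with t reset to 0, and an M -> G1 move increments
// the division round and appends a daughter identical to the updated
// parent. Daughters are appended after all parents and are not processed
// until the next step.
//
// mu, sigma: 4 x 2 matrices (rows G1,S,G2,M; col 0 = round 0, col 1 = rounds
// >= 1). b: per-phase blocking probabilities, applied only when bActive.
// [[Rcpp::export]]
List cpp_advance(IntegerVector phase, NumericVector t, IntegerVector round,
                 LogicalVector arrested, NumericMatrix mu, NumericMatrix sigma,
                 double shape, NumericVector b, bool bActive, double dT,
                 double guard) {
  int n = phase.size();
  std::vector<int> ph(phase.begin(), phase.end());
  std::vector<double> tt(t.begin(), t.end());
  std::vector<int> rd(round.begin(), round.end());
  std::vector<int> ar(arrested.begin(), arrested.end());
  ph.reserve(n + n / 8 + 8);
  tt.reserve(n + n / 8 + 8);
  rd.reserve(n + n / 8 + 8);
  ar.reserve(n + n / 8 + 8);
  int divisions = 0;

  for (int i = 0; i < n; ++i) {
    double u1 = unif_rand();
    if (ar[i]) { tt[i] += dT; continue; }
    int col = (rd[i] == 0) ? 0 : 1;
    int p = ph[i] - 1;
    double prob = hazard(tt[i], dT, mu(p, col), sigma(p, col), shape, guard);
    if (u1 < prob) {
      double u2 = unif_rand();
      double beff = bActive ? b[p] : 0.0;
      if (u2 < beff) {
        tt[i] += dT;              // blocked: stay in phase, keep ageing
      } else if (ph[i] == 4) {    // M -> G1: mitosis
        ph[i] = 1;
        rd[i] += 1;
        tt[i] = 0.0;
        ph.push_back(1);
        tt.push_back(0.0);
        rd.push_back(rd[i]);
        ar.push_back(0);
        ++divisions;
      } else {
        ph[i] += 1;
        tt[i] = 0.0;
      }
    } else {
      tt[i] += dT;
    }
  }

  return List::create(
    _["phase"] = IntegerVector(ph.begin(), ph.end()),
    _["t"] = NumericVector(tt.begin(), tt.end()),
    _["round"] = IntegerVector(rd.begin(), rd.end()),
    _["arrested"] = LogicalVector(ar.begin(), ar.end()),
    _["divisions"] = divisions);
}
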