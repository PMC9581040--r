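#include <Rcpp.h>
using namespace Rcpp;

// Whole-schedule simulation loop. Identical update rule and random-number
// consumption to cpp_advance (one uniform per cell per step in stable index
// order, one extra uniform per attempted transition), but runs all steps in
// one call and caches each cell's current CDF value F(t): advancing t by dT
// reuses last step's F(t + dT), so at most one CDF evaluation per cell per
// step is needed, and none at all while t + dT is still below the law's
// support endpoint.

static inline double gev_cdf2(double t, double mu, double sigma, double xi) {
  double z = 1.0 + xi * (t - mu) / sigma;
  if (z <= 0.0) return 0.0;
  return std::exp(-std::pow(z, -1.0 / xi));
}

// Blocking is active during (1-based) step k iff k - 1 >= drugStep and
// drugStep >= 0. snapSteps are 0-based step indices (0 = initial state)
// at which full population snapshots are returned, in the given order.
// [[Rcpp::export]]
List cpp_simulate(IntegerVector phase, NumericVector t, IntegerVector round,
                  LogicalVector arrested, NumericMatrix mu,
                  NumericMatrix sigma, double shape, NumericVector b,
                  int drugStep, double dT, double guard, int nsteps,
                  IntegerVector snapSteps) {
  int n = phase.size();
  std::vector<int> ph(phase.begin(), phase.end());
  std::vector<double> tt(t.begin(), t.end());
  std::vector<int> rd(round.begin(), round.end());
  std::vector<int> ar(arrested.begin(), arrested.end());
  std::vector<double> Fc(n);
  double invxi = 1.0 / shape;
  (void)invxi;

  for (int i = 0; i < n; ++i) {
    int col = (rd[i] == 0) ? 0 : 1;
    Fc[i] = gev_cdf2(tt[i], mu(ph[i] - 1, col), sigma(ph[i] - 1, col),
                     shape);
  }

  int nsnap = snapSteps.size();
  List snaps(nsnap);
  auto record = [&](int k) {
    for (int s = 0; s < nsnap; ++s) {
      if (snapSteps[s] == k) {
        snaps[s] = List::create(
          _["phase"] = IntegerVector(ph.begin(), ph.end()),
          _["t"] = NumericVector(tt.begin(), tt.end()),
          _["round"] = IntegerVector(rd.begin(), rd.end()),
          _["arrested"] = LogicalVector(ar.begin(), ar.end()));
      }
    }
  };
  record(0);

  for (int k = 1; k <= nsteps; ++k) {
    bool bActive = (drugStep >= 0) && (k - 1 >= drugStep);
    int ncur = (int)ph.size();
    for (int i = 0; i < ncur; ++i) {
      double u1 = unif_rand();
      if (ar[i]) { tt[i] += dT; continue; }
      int col = (rd[i] == 0) ? 0 : 1;
      int p = ph[i] - 1;
      double f0 = Fc[i];
      double surv = 1.0 - f0;
      double prob;
      double f1 = gev_cdf2(tt[i] + dT, mu(p, col), sigma(p, col), shape);
      if (surv < guard) prob = 1.0;
      else {
        prob = (f1 - f0) / surv;
        if (prob < 0.0) prob = 0.0;
        if (prob > 1.0) prob = 1.0;
      }
      if (u1 < prob) {
        double u2 = unif_rand();
        double beff = bActive ? b[p] : 0.0;
        if (u2 < beff) {
          tt[i] += dT;
          Fc[i] = f1;
        } else if (ph[i] == 4) {   // mitosis
          ph[i] = 1;
          rd[i] += 1;
          tt[i] = 0.0;
          int ncol = (rd[i] == 0) ? 0 : 1;
          Fc[i] = gev_cdf2(0.0, mu(0, ncol), sigma(0, ncol), shape);
          ph.push_back(1);
          tt.push_back(0.0);
          rd.push_back(rd[i]);
          ar.push_back(0);
          Fc.push_back(Fc[i]);
        } else {
          ph[i] += 1;
          tt[i] = 0.0;
          Fc[i] = gev_cdf2(0.0, mu(ph[i] - 1, col), sigma(ph[i] - 1, col),
                           shape);
        }
      } else {
        tt[i] += dT;
        Fc[i] = f1;
      }
    }
    record(k);
  }

  return List::create(
    _["snapshots"] = snaps,
    _["final"] = List::create(
      _["phase"] = IntegerVector(ph.begin(), ph.end()),
      _["t"] = NumericVector(tt.begin(), tt.end()),
      _["round"] = IntegerVector(rd.begin(), rd.end()),
      _["arrested"] = LogicalVector(ar.begin(), ar.end())));
}
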