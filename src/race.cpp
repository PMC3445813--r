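#include <Rcpp.h>
using namespace Rcpp;

// LBA race over the valid accumulators of n trials of one condition.
//
// mu, sd, b, c0, t0 are length-4 vectors indexed by action id; V maps each
// trial x slot to an action id; M marks slots receiving the condition's
// modulation ratios (r_mu, r_b, r_t0). Z and U are pre-drawn standard-normal
// and uniform(0,1) variates, so repeated calls with the same draws trace a
// deterministic objective surface (common random numbers).
//
// Effective parameters depend only on (action, modulated?) so they are
// precomputed into 4 x 2 tables; the race itself streams column-wise over
// contiguous memory and keeps a running minimum finishing time per trial.

static const double T_BIG = 1e30;

struct EffTables {
  double mu[8], sd[8], b[8], c0[8], t0[8]; // [m * 4 + a], m = modulated
};

static EffTables make_tables(const NumericVector &mu, const NumericVector &sd,
                             const NumericVector &b, const NumericVector &c0,
                             const NumericVector &t0,
                             double r_mu, double r_b, double r_t0) {
  EffTables e;
  for (int a = 0; a < 4; ++a) {
    e.mu[a] = mu[a];        e.mu[4 + a] = mu[a] * r_mu;
    e.b[a] = b[a];          e.b[4 + a] = b[a] * r_b;
    e.t0[a] = t0[a];        e.t0[4 + a] = t0[a] * r_t0;
    e.sd[a] = sd[a];        e.sd[4 + a] = sd[a];
    e.c0[a] = c0[a];        e.c0[4 + a] = c0[a];
  }
  return e;
}

// one slot column: update per-trial best finishing time and winning slot
static void race_column(const EffTables &e, int n, int j,
                        const int *v, const int *m,
                        const double *z, const double *u,
                        double *best, int *slot) {
  for (int i = 0; i < n; ++i) {
    int idx = (m[i] ? 4 : 0) + (v[i] - 1);
    double rate = e.mu[idx] + e.sd[idx] * z[i];
    double gap = e.b[idx] - e.c0[idx] * u[i];
    if (gap < 0.0) gap = 0.0;
    double t = (rate > 0.0) ? gap / rate + e.t0[idx] : T_BIG;
    if (t < best[i]) { best[i] = t; slot[i] = j + 1; }
  }
}

static void run_race(const NumericVector &mu, const NumericVector &sd,
                     const NumericVector &b, const NumericVector &c0,
                     const NumericVector &t0,
                     double r_mu, double r_b, double r_t0,
                     const IntegerMatrix &V, const LogicalMatrix &M,
                     const NumericMatrix &Z, const NumericMatrix &U,
                     std::vector<double> &best, std::vector<int> &slot) {
  int n = V.nrow(), k = V.ncol();
  EffTables e = make_tables(mu, sd, b, c0, t0, r_mu, r_b, r_t0);
  best.assign(n, T_BIG);
  slot.assign(n, 0);
  for (int j = 0; j < k; ++j)
    race_column(e, n, j, &V[(R_xlen_t)j * n], &M[(R_xlen_t)j * n],
                &Z[(R_xlen_t)j * n], &U[(R_xlen_t)j * n],
                best.data(), slot.data());
}

// [[Rcpp::export]]
List race_sim_cpp(NumericVector mu, NumericVector sd, NumericVector b,
                  NumericVector c0, NumericVector t0,
                  double r_mu, double r_b, double r_t0,
                  IntegerMatrix V, LogicalMatrix M,
                  NumericMatrix Z, NumericMatrix U, double deadline) {
  int n = V.nrow();
  std::vector<double> best;
  std::vector<int> slot;
  run_race(mu, sd, b, c0, t0, r_mu, r_b, r_t0, V, M, Z, U, best, slot);
  NumericVector rt(n);
  IntegerVector winner(n), wslot(n);
  for (int i = 0; i < n; ++i) {
    if (slot[i] == 0 || best[i] > deadline) {
      rt[i] = NA_REAL; winner[i] = NA_INTEGER; wslot[i] = NA_INTEGER;
    } else {
      rt[i] = best[i]; winner[i] = V(i, slot[i] - 1); wslot[i] = slot[i];
    }
  }
  return List::create(_["rt"] = rt, _["winner"] = winner, _["slot"] = wslot);
}

// Fitting fast path: returns only the counts the G-squared objective needs.
// edges are the observed RT quantiles (bin boundaries); catmap assigns each
// trial x slot to a selection category in 1..ncat (0 = uncategorized).
// [[Rcpp::export]]
List race_fit_cpp(NumericVector mu, NumericVector sd, NumericVector b,
                  NumericVector c0, NumericVector t0,
                  double r_mu, double r_b, double r_t0,
                  IntegerMatrix V, LogicalMatrix M,
                  NumericMatrix Z, NumericMatrix U, double deadline,
                  NumericVector edges, IntegerMatrix catmap, int ncat) {
  int n = V.nrow(), ne = edges.size();
  std::vector<double> best;
  std::vector<int> slot;
  run_race(mu, sd, b, c0, t0, r_mu, r_b, r_t0, V, M, Z, U, best, slot);
  IntegerVector bins(ne + 1), cats(ncat);
  int n_resp = 0, n_omit = 0;
  const double *ed = edges.begin();
  for (int i = 0; i < n; ++i) {
    if (slot[i] == 0 || best[i] > deadline) { ++n_omit; continue; }
    ++n_resp;
    double t = best[i];
    int bin = 0;
    while (bin < ne && t > ed[bin]) ++bin;
    ++bins[bin];
    if (ncat > 1) {
      int c = catmap(i, slot[i] - 1);
      if (c >= 1 && c <= ncat) ++cats[c - 1];
    } else ++cats[0];
  }
  return List::create(_["bins"] = bins, _["cats"] = cats,
                      _["n_resp"] = n_resp, _["n_omit"] = n_omit);
}
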