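#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact two-sided Fisher test for an r x 2 table by full enumeration of the
// hypergeometric support with the observed margins. Two-sided rule: sum the
// point probabilities of every table whose probability is <= (1 + rel_tol)
// times the observed table's. Enumeration: nested loops over the first r-1
// cells of column 1 with feasibility pruning; the last row is determined by
// the column margin. Per-table log-probability is a sum of per-row
// log-binomials minus the margin log-binomial.

static double lchoose_(double n, double k) {
  return std::lgamma(n + 1.0) - std::lgamma(k + 1.0) - std::lgamma(n - k + 1.0);
}

struct Enumerator {
  int r;
  std::vector<int> rowtot;
  int n1;
  double denom;       // log C(N, n1)
  double thr;         // log threshold
  long double p_sum;  // two-sided mass
  long double total;  // total mass over the support (should be 1)
  double budget;
  double evaluated;
  std::vector<std::vector<double>> lb;  // lb[i][x] = log C(rowtot[i], x)
  std::vector<int> suffix_cap;          // max attainable sum of rows i..r-1

  void recurse(int row, int rem, double acc) {
    if (evaluated > budget) stop("fisher_exact_rx2: enumeration budget exceeded; use the Monte-Carlo fallback");
    if (row == r - 1) {
      // last cell fixed by the column margin
      if (rem < 0 || rem > rowtot[row]) return;
      double lp = acc + lb[row][rem] - denom;
      long double p = expl((long double)lp);
      total += p;
      if (lp <= thr) p_sum += p;
      evaluated += 1;
      return;
    }
    int lo = std::max(0, rem - suffix_cap[row + 1]);
    int hi = std::min(rowtot[row], rem);
    for (int x = lo; x <= hi; ++x)
      recurse(row + 1, rem - x, acc + lb[row][x]);
  }
};

// [[Rcpp::export]]
List fisher_rx2_cpp(IntegerMatrix counts, double rel_tol = 1e-7,
                    double budget = 1e9) {
  int r = counts.nrow();
  if (counts.ncol() != 2) stop("fisher_rx2_cpp: table must have 2 columns");
  if (r < 2) stop("fisher_rx2_cpp: need at least 2 rows");

  Enumerator e;
  e.r = r;
  e.n1 = 0;
  int N = 0;
  e.rowtot.resize(r);
  for (int i = 0; i < r; ++i) {
    if (counts(i, 0) < 0 || counts(i, 1) < 0) stop("fisher_rx2_cpp: negative count");
    e.rowtot[i] = counts(i, 0) + counts(i, 1);
    e.n1 += counts(i, 0);
    N += e.rowtot[i];
  }
  // degenerate margins: a single table is possible
  if (e.n1 == 0 || e.n1 == N)
    return List::create(_["p"] = 1.0, _["tables"] = 1.0,
                        _["log_p_obs"] = 0.0, _["total_mass"] = 1.0);

  e.denom = lchoose_(N, e.n1);
  e.lb.resize(r);
  for (int i = 0; i < r; ++i) {
    e.lb[i].resize(e.rowtot[i] + 1);
    for (int x = 0; x <= e.rowtot[i]; ++x)
      e.lb[i][x] = lchoose_((double)e.rowtot[i], (double)x);
  }
  e.suffix_cap.assign(r + 1, 0);
  for (int i = r - 1; i >= 0; --i)
    e.suffix_cap[i] = e.suffix_cap[i + 1] + e.rowtot[i];

  double lp_obs = -e.denom;
  for (int i = 0; i < r; ++i) lp_obs += e.lb[i][counts(i, 0)];
  e.thr = lp_obs + std::log1p(rel_tol);
  e.p_sum = 0.0L;
  e.total = 0.0L;
  e.budget = budget;
  e.evaluated = 0.0;

  e.recurse(0, e.n1, 0.0);

  double p = (double)e.p_sum;
  if (p > 1.0) p = 1.0;
  return List::create(_["p"] = p, _["tables"] = e.evaluated,
                      _["log_p_obs"] = lp_obs,
                      _["total_mass"] = (double)e.total);
}
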