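#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local cost of matching event i of A to event j of B, both already on the
// model scale (time in hours, energy in 100-kcal units by default):
// (de)^2 + beta * (dt)^2.
static inline double local_cost(double ta, double ea, double tb, double eb,
                                double beta) {
  double de = ea - eb;
  double dt = ta - tb;
  return de * de + beta * dt * dt;
}

// Classic DTW dynamic programme over the |A| x |B| alignment table with the
// match / repeat-left / repeat-right step set and no window constraint.
// Two-row rolling buffer; sequences are short (eating events per day).
static double mdtw_core(const double* ta, const double* ea, int na,
                        const double* tb, const double* eb, int nb,
                        double beta, std::vector<double>& prev,
                        std::vector<double>& curr) {
  prev.resize(nb);
  curr.resize(nb);
  prev[0] = local_cost(ta[0], ea[0], tb[0], eb[0], beta);
  for (int j = 1; j < nb; ++j)
    prev[j] = prev[j - 1] + local_cost(ta[0], ea[0], tb[j], eb[j], beta);
  for (int i = 1; i < na; ++i) {
    curr[0] = prev[0] + local_cost(ta[i], ea[i], tb[0], eb[0], beta);
    for (int j = 1; j < nb; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (curr[j - 1] < best) best = curr[j - 1];
      curr[j] = best + local_cost(ta[i], ea[i], tb[j], eb[j], beta);
    }
    std::swap(prev, curr);
  }
  return prev[nb - 1];
}

// [[Rcpp::export]]
double mdtw_dist_cpp(NumericVector ta, NumericVector ea, NumericVector tb,
                     NumericVector eb, double beta) {
  std::vector<double> p, c;
  return mdtw_core(ta.begin(), ea.begin(), ta.size(), tb.begin(), eb.begin(),
                   tb.size(), beta, p, c);
}

// Pairwise distances for a cohort: events are concatenated participant-wise,
// with 0-based offsets `start` and lengths `len` per participant.
// [[Rcpp::export]]
NumericMatrix mdtw_pairwise_cpp(NumericVector t, NumericVector e,
                                IntegerVector start, IntegerVector len,
                                double beta) {
  int n = start.size();
  NumericMatrix D(n, n);
  std::vector<double> p, c;
  const double* tp = t.begin();
  const double* ep = e.begin();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = mdtw_core(tp + start[i], ep + start[i], len[i],
                           tp + start[j], ep + start[j], len[j], beta, p, c);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
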