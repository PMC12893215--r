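#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Segment cost interface. Segments are half-open [s, t) in 0-based sample
// indices. Both costs are additive over segments so PELT pruning is exact
// (pruning constant K = 0).

class MeanCost {
  // Gaussian mean-shift cost: RSS about the segment mean. The caller is
  // expected to scale the series to (approximately) unit noise variance so
  // that log-n penalties behave like BIC.
  std::vector<double> s1, s2;
public:
  explicit MeanCost(const NumericVector& x) {
    int n = x.size();
    s1.assign(n + 1, 0.0);
    s2.assign(n + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      s1[i + 1] = s1[i] + x[i];
      s2[i + 1] = s2[i] + x[i] * x[i];
    }
  }
  double operator()(int s, int t) const {
    double len = t - s;
    double a = s1[t] - s1[s];
    return (s2[t] - s2[s]) - a * a / len;
  }
};

class EDCost {
  // Empirical-distribution (nonparametric maximum likelihood) cost over K
  // quantile levels of the full series, with the usual 0.5 weighting of
  // ties; K = ceil(log n). Rank-based, hence invariant under monotone
  // transforms of the data.
  int K;
  double c0;
  std::vector<std::vector<double>> cum; // cum[k][i]: weighted count over [0, i)
public:
  explicit EDCost(const NumericVector& x) {
    int n = x.size();
    K = std::max(1, (int)std::ceil(std::log((double)n)));
    c0 = 2.0 * std::log(2.0 * n - 1.0) / K;
    NumericVector xs = clone(x);
    std::sort(xs.begin(), xs.end());
    cum.assign(K, std::vector<double>(n + 1, 0.0));
    for (int k = 0; k < K; ++k) {
      // quantile levels at probabilities (k + 0.5) / K (type-1 style)
      double p = (k + 0.5) / K;
      int idx = std::min(n - 1, (int)std::floor(p * n));
      double tk = xs[idx];
      for (int i = 0; i < n; ++i) {
        double w = x[i] < tk ? 1.0 : (x[i] == tk ? 0.5 : 0.0);
        cum[k][i + 1] = cum[k][i] + w;
      }
    }
  }
  double operator()(int s, int t) const {
    double len = t - s;
    double cost = 0.0;
    for (int k = 0; k < K; ++k) {
      double p = (cum[k][t] - cum[k][s]) / len;
      if (p > 0.0 && p < 1.0)
        cost -= len * (p * std::log(p) + (1.0 - p) * std::log(1.0 - p));
    }
    return c0 * cost;
  }
};

template <class Cost>
static IntegerVector pelt(const Cost& C, int n, double beta, int minlen) {
  // With a minimum segment length the textbook pruning rule is not safe at
  // horizons closer than minlen (the dominating candidate is not yet a
  // legal change point there), so a candidate is dropped only after the
  // domination condition has held for minlen consecutive steps.
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> F(n + 1, INF);
  std::vector<int> prev(n + 1, 0);
  F[0] = -beta;
  std::vector<int> cand, failed;
  cand.push_back(0);
  failed.push_back(0);
  for (int t = minlen; t <= n; ++t) {
    double best = INF;
    int arg = 0;
    for (size_t i = 0; i < cand.size(); ++i) {
      int s = cand[i];
      if (t - s < minlen) continue;
      double v = F[s] + C(s, t) + beta;
      if (v < best) { best = v; arg = s; }
    }
    F[t] = best;
    prev[t] = arg;
    std::vector<int> kc, kf;
    for (size_t i = 0; i < cand.size(); ++i) {
      int s = cand[i];
      int f = failed[i];
      if (t - s >= minlen && F[s] + C(s, t) > F[t]) ++f; else f = 0;
      if (f < minlen) { kc.push_back(s); kf.push_back(f); }
    }
    cand = kc; failed = kf;
    cand.push_back(t);
    failed.push_back(0);
  }
  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    int s = prev[t];
    if (s > 0) cps.push_back(s);
    t = s;
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps); // 0-based index of first sample of each new segment
}

template <class Cost>
static void binseg_rec(const Cost& C, int a, int b, double beta, int minlen,
                       std::vector<int>& out) {
  if (b - a < 2 * minlen) return;
  double whole = C(a, b);
  double best = std::numeric_limits<double>::infinity();
  int arg = -1;
  for (int s = a + minlen; s <= b - minlen; ++s) {
    double v = C(a, s) + C(s, b);
    if (v < best) { best = v; arg = s; }
  }
  if (arg >= 0 && whole - best > beta) {
    out.push_back(arg);
    binseg_rec(C, a, arg, beta, minlen, out);
    binseg_rec(C, arg, b, beta, minlen, out);
  }
}

template <class Cost>
static IntegerVector binseg(const Cost& C, int n, double beta, int minlen) {
  std::vector<int> cps;
  binseg_rec(C, 0, n, beta, minlen, cps);
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}

// [[Rcpp::export(name = ".cpt_mean_pelt")]]
IntegerVector cpt_mean_pelt(NumericVector x, double beta, int minlen = 2) {
  MeanCost C(x);
  return pelt(C, x.size(), beta, minlen);
}

// [[Rcpp::export(name = ".cpt_mean_binseg")]]
IntegerVector cpt_mean_binseg(NumericVector x, double beta, int minlen = 2) {
  MeanCost C(x);
  return binseg(C, x.size(), beta, minlen);
}

// [[Rcpp::export(name = ".cpt_np_pelt")]]
IntegerVector cpt_np_pelt(NumericVector x, double beta, int minlen = 2) {
  EDCost C(x);
  return pelt(C, x.size(), beta, minlen);
}

// [[Rcpp::export(name = ".cpt_np_binseg")]]
IntegerVector cpt_np_binseg(NumericVector x, double beta, int minlen = 2) {
  EDCost C(x);
  return binseg(C, x.size(), beta, minlen);
}

// [[Rcpp::export(name = ".cpt_mean_cost")]]
double cpt_mean_cost(NumericVector x, IntegerVector cps, double beta) {
  // total penalized cost of a segmentation (0-based segment starts), for
  // cross-checking PELT against an exhaustive dynamic-programming oracle
  MeanCost C(x);
  int n = x.size();
  std::vector<int> b(cps.begin(), cps.end());
  std::sort(b.begin(), b.end());
  b.push_back(n);
  double tot = beta * (double)cps.size();
  int a = 0;
  for (int e : b) { tot += C(a, e); a = e; }
  return tot;
}
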