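// Risk-set sweep for the partial likelihood on counting-process rows.
//
// Risk set at event time t: rows with entry < t <= exit. Sums over risk
// sets use sum_{entry < t <= exit} = sum_{exit >= t} - sum_{entry >= t}
// (exit > entry row-wise), each side accumulated by a descending sweep over
// the distinct event times with a sorted-row pointer, so one evaluation is
// O(n log n + (n + K) p^2).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".cox_eval_cpp")]]
List cox_eval_cpp(NumericVector entry, NumericVector exit,
                  IntegerVector event, NumericMatrix X,
                  NumericVector beta, bool need_hess) {
  const int n = X.nrow(), p = X.ncol();

  NumericVector lp(n), w(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    lp[i] = s;
    w[i] = std::exp(s);
  }

  // distinct event times (ascending) and their multiplicities
  std::vector<double> dtimes;
  for (int i = 0; i < n; ++i)
    if (event[i] == 1) dtimes.push_back(exit[i]);
  std::sort(dtimes.begin(), dtimes.end());
  std::vector<double> d;
  std::vector<double> m;
  for (size_t i = 0; i < dtimes.size(); ++i) {
    if (d.empty() || dtimes[i] != d.back()) {
      d.push_back(dtimes[i]);
      m.push_back(1.0);
    } else {
      m.back() += 1.0;
    }
  }
  const int K = (int)d.size();

  std::vector<int> ob(n), oa(n);  // rows by descending exit / entry
  for (int i = 0; i < n; ++i) ob[i] = oa[i] = i;
  std::sort(ob.begin(), ob.end(),
            [&](int i, int j) { return exit[i] > exit[j]; });
  std::sort(oa.begin(), oa.end(),
            [&](int i, int j) { return entry[i] > entry[j]; });

  const int q = p * (p + 1) / 2;
  std::vector<double> S0b(1, 0.0), S0a(1, 0.0);
  std::vector<double> S1b(p, 0.0), S1a(p, 0.0);
  std::vector<double> S2b(q, 0.0), S2a(q, 0.0);

  NumericVector S0(K);
  NumericMatrix xbar(K, p);
  NumericVector loglik(1);
  NumericVector score(p);
  NumericMatrix info(p, p);
  std::vector<double> s2tmp(q, 0.0);
  bool ok = true;

  double ll = 0.0;
  for (int i = 0; i < n; ++i)
    if (event[i] == 1) {
      ll += lp[i];
      for (int j = 0; j < p; ++j) score[j] += X(i, j);
    }

  int ib = 0, ia = 0;
  for (int k = K - 1; k >= 0; --k) {
    const double t = d[k];
    while (ib < n && exit[ob[ib]] >= t) {
      const int r = ob[ib];
      S0b[0] += w[r];
      for (int j = 0; j < p; ++j) S1b[j] += w[r] * X(r, j);
      if (need_hess) {
        int c = 0;
        for (int j = 0; j < p; ++j)
          for (int i2 = 0; i2 <= j; ++i2, ++c)
            S2b[c] += w[r] * X(r, i2) * X(r, j);
      }
      ++ib;
    }
    while (ia < n && entry[oa[ia]] >= t) {
      const int r = oa[ia];
      S0a[0] += w[r];
      for (int j = 0; j < p; ++j) S1a[j] += w[r] * X(r, j);
      if (need_hess) {
        int c = 0;
        for (int j = 0; j < p; ++j)
          for (int i2 = 0; i2 <= j; ++i2, ++c)
            S2a[c] += w[r] * X(r, i2) * X(r, j);
      }
      ++ia;
    }
    const double s0 = S0b[0] - S0a[0];
    S0[k] = s0;
    if (s0 <= 0.0) { ok = false; continue; }
    ll -= m[k] * std::log(s0);
    for (int j = 0; j < p; ++j) {
      xbar(k, j) = (S1b[j] - S1a[j]) / s0;
      score[j] -= m[k] * xbar(k, j);
    }
    if (need_hess) {
      int c = 0;
      for (int j = 0; j < p; ++j)
        for (int i2 = 0; i2 <= j; ++i2, ++c) {
          const double v =
              m[k] * ((S2b[c] - S2a[c]) / s0 - xbar(k, i2) * xbar(k, j));
          info(i2, j) += v;
          if (i2 != j) info(j, i2) += v;
        }
    }
  }

  loglik[0] = ok ? ll : R_NegInf;
  return List::create(_["loglik"] = loglik[0], _["score"] = score,
                      _["info"] = info, _["d"] = wrap(d), _["m"] = wrap(m),
                      _["S0"] = S0, _["xbar"] = xbar, _["lp"] = lp,
                      _["w"] = w, _["ok"] = ok);
}
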