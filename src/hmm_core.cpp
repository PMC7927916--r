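#include <Rcpp.h>
using namespace Rcpp;

// Log-domain forward-backward and Viterbi for one sequence.
// logB: T x K matrix of log emission probabilities; logpi: length K;
// logP: K x K with logP(i,j) = log P(s_{t+1}=j | s_t=i).

static double logsumexp_row(const NumericVector& v) {
  double m = max(v);
  if (!R_finite(m)) return m; // all -Inf
  double s = 0.0;
  for (int i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List fb_one_cpp(NumericMatrix logB, NumericVector logpi, NumericMatrix logP) {
  int T = logB.nrow(), K = logB.ncol();
  NumericMatrix la(T, K), lb(T, K);
  // forward
  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      NumericVector tmp(K);
      for (int i = 0; i < K; ++i) tmp[i] = la(t - 1, i) + logP(i, k);
      la(t, k) = logsumexp_row(tmp) + logB(t, k);
    }
  }
  NumericVector last = la(T - 1, _);
  double ll = logsumexp_row(last);
  if (!R_finite(ll))
    stop("data have zero probability under the model (all-impossible emission)");
  // backward
  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      NumericVector tmp(K);
      for (int j = 0; j < K; ++j) tmp[j] = logP(k, j) + logB(t + 1, j) + lb(t + 1, j);
      lb(t, k) = logsumexp_row(tmp);
    }
  }
  // posteriors
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) gamma(t, k) = std::exp(la(t, k) + lb(t, k) - ll);
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += gamma(t, k);
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  // summed pairwise posteriors
  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    double norm = 0.0;
    NumericMatrix e(K, K);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        double v = la(t, i) + logP(i, j) + logB(t + 1, j) + lb(t + 1, j) - ll;
        e(i, j) = std::exp(v);
        norm += e(i, j);
      }
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) xi(i, j) += e(i, j) / norm;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Aggregate E-step over a list of per-trial logB matrices.
// Returns total loglik, summed xi, summed first-bin posteriors, and the
// per-bin posteriors stacked row-wise in trial order (for the emission
// M-step, which multiplies counts against them in R).
// [[Rcpp::export]]
List fb_all_cpp(List logB_list, NumericVector logpi, NumericMatrix logP) {
  int M = logB_list.size(), K = logpi.size();
  int Ttot = 0;
  for (int m = 0; m < M; ++m) Ttot += as<NumericMatrix>(logB_list[m]).nrow();
  NumericMatrix gamma_all(Ttot, K), xi(K, K);
  NumericVector g1(K);
  double ll = 0.0;
  int off = 0;
  for (int m = 0; m < M; ++m) {
    NumericMatrix logB = logB_list[m];
    List r = fb_one_cpp(logB, logpi, logP);
    NumericMatrix g = r["gamma"], x = r["xi"];
    ll += as<double>(r["loglik"]);
    int T = g.nrow();
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) gamma_all(off + t, k) = g(t, k);
    for (int i = 0; i < K; ++i) {
      g1[i] += g(0, i);
      for (int j = 0; j < K; ++j) xi(i, j) += x(i, j);
    }
    off += T;
  }
  return List::create(_["gamma"] = gamma_all, _["xi"] = xi,
                      _["gamma1"] = g1, _["loglik"] = ll);
}

// Viterbi for one sequence; ties broken toward the lower state index
// (strict improvement required to switch). Returns 1-based states.
// [[Rcpp::export]]
IntegerVector viterbi_one_cpp(NumericMatrix logB, NumericVector logpi,
                              NumericMatrix logP) {
  int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      int best = 0;
      double bv = delta(t - 1, 0) + logP(0, k);
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logP(i, k);
        if (v > bv) { bv = v; best = i; }
      }
      delta(t, k) = bv + logB(t, k);
      psi(t, k) = best;
    }
  }
  IntegerVector path(T);
  int best = 0;
  double bv = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > bv) { bv = delta(T - 1, k); best = k; }
  if (!R_finite(bv))
    stop("data have zero probability under the model (all-impossible emission)");
  path[T - 1] = best;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
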