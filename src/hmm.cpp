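#include <Rcpp.h>
using namespace Rcpp;

// All routines work in log space on one class block at a time: logpi is the
// (possibly unnormalized) initial log-mass of the block's states, logA the
// block's row-stochastic transition matrix in logs, and logB a T x n matrix
// of per-event emission log-densities. Sequences are short (tens of events)
// and blocks small (<= 5 states), so the plain O(T n^2) recursions suffice.

static inline double logsumexp(const double* v, int n) {
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) if (v[i] > m) m = v[i];
  if (!R_FINITE(m)) return R_NegInf;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List cpp_forward(NumericVector logpi, NumericMatrix logA, NumericMatrix logB) {
  const int T = logB.nrow(), n = logB.ncol();
  NumericMatrix la(T, n);
  std::vector<double> tmp(n);
  for (int i = 0; i < n; ++i) la(0, i) = logpi[i] + logB(0, i);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) tmp[i] = la(t - 1, i) + logA(i, j);
      la(t, j) = logsumexp(tmp.data(), n) + logB(t, j);
    }
  NumericVector term(n);
  for (int i = 0; i < n; ++i) term[i] = la(T - 1, i);
  double ll = logsumexp(&term[0], n);
  return List::create(_["loglik"] = ll, _["log_alpha_T"] = term);
}

// Per-sequence log-likelihoods for a batch of sequences stacked in logB_all
// (rows grouped by sequence, lengths in lens).
// [[Rcpp::export]]
NumericVector cpp_forward_batch(NumericVector logpi, NumericMatrix logA,
                                NumericMatrix logB_all, IntegerVector lens) {
  const int n = logB_all.ncol(), S = lens.size();
  NumericVector out(S);
  std::vector<double> prev(n), cur(n), tmp(n);
  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lens[s];
    for (int i = 0; i < n; ++i) prev[i] = logpi[i] + logB_all(off, i);
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < n; ++j) {
        for (int i = 0; i < n; ++i) tmp[i] = prev[i] + logA(i, j);
        cur[j] = logsumexp(tmp.data(), n) + logB_all(off + t, j);
      }
      prev = cur;
    }
    out[s] = logsumexp(prev.data(), n);
    off += T;
  }
  return out;
}

// Forward-backward expected sufficient statistics over a batch, each
// sequence's contribution scaled by w[s]. Emission features run parallel to
// logB_all's rows: xfd (always valid), xsl + categorical sd (valid where
// sl_ok != 0, i.e. all but the last fixation), aoi in 1..4, sd in 1..4 or 0.
// [[Rcpp::export]]
List cpp_estep_batch(NumericVector logpi, NumericMatrix logA,
                     NumericMatrix logB_all, IntegerVector lens,
                     NumericVector w, NumericVector xfd, NumericVector xsl,
                     IntegerVector aoi, IntegerVector sd, IntegerVector sl_ok) {
  const int n = logB_all.ncol(), S = lens.size();
  int Tmax = 0;
  for (int s = 0; s < S; ++s) if (lens[s] > Tmax) Tmax = lens[s];

  NumericVector pi_counts(n), swt(n), sfd(n), sfd2(n), swl(n), ssl(n), ssl2(n);
  NumericMatrix trans(n, n), aoi_counts(n, 4), sd_counts(n, 4);
  double total_ll = 0.0;

  std::vector<double> la(Tmax * n), lb(Tmax * n), tmp(n), gam(n);
  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lens[s];
    const double ws = w[s];
    // forward
    for (int i = 0; i < n; ++i) la[i] = logpi[i] + logB_all(off, i);
    for (int t = 1; t < T; ++t)
      for (int j = 0; j < n; ++j) {
        for (int i = 0; i < n; ++i) tmp[i] = la[(t - 1) * n + i] + logA(i, j);
        la[t * n + j] = logsumexp(tmp.data(), n) + logB_all(off + t, j);
      }
    const double ll = logsumexp(&la[(T - 1) * n], n);
    total_ll += ws * ll;
    if (!R_FINITE(ll)) { off += T; continue; }
    // backward
    for (int i = 0; i < n; ++i) lb[(T - 1) * n + i] = 0.0;
    for (int t = T - 2; t >= 0; --t)
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j)
          tmp[j] = logA(i, j) + logB_all(off + t + 1, j) + lb[(t + 1) * n + j];
        lb[t * n + i] = logsumexp(tmp.data(), n);
      }
    // gamma accumulation
    for (int t = 0; t < T; ++t) {
      const int r = off + t;
      for (int i = 0; i < n; ++i) {
        double g = std::exp(la[t * n + i] + lb[t * n + i] - ll);
        gam[i] = g;
        const double wg = ws * g;
        swt[i] += wg;
        sfd[i] += wg * xfd[r];
        sfd2[i] += wg * xfd[r] * xfd[r];
        if (aoi[r] >= 1 && aoi[r] <= 4) aoi_counts(i, aoi[r] - 1) += wg;
        if (sl_ok[r]) {
          swl[i] += wg;
          ssl[i] += wg * xsl[r];
          ssl2[i] += wg * xsl[r] * xsl[r];
          if (sd[r] >= 1 && sd[r] <= 4) sd_counts(i, sd[r] - 1) += wg;
        }
      }
      if (t == 0)
        for (int i = 0; i < n; ++i) pi_counts[i] += ws * gam[i];
    }
    // xi accumulation
    for (int t = 0; t < T - 1; ++t)
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
          double x = std::exp(la[t * n + i] + logA(i, j) +
                              logB_all(off + t + 1, j) + lb[(t + 1) * n + j] - ll);
          trans(i, j) += ws * x;
        }
    off += T;
  }
  return List::create(
      _["loglik"] = total_ll, _["pi_counts"] = pi_counts, _["trans"] = trans,
      _["swt"] = swt, _["sfd"] = sfd, _["sfd2"] = sfd2, _["swl"] = swl,
      _["ssl"] = ssl, _["ssl2"] = ssl2, _["aoi_counts"] = aoi_counts,
      _["sd_counts"] = sd_counts);
}

// Most probable state path; ties broken toward the lowest state index
// (strict > comparison keeps the earlier candidate).
// [[Rcpp::export]]
List cpp_viterbi(NumericVector logpi, NumericMatrix logA, NumericMatrix logB) {
  const int T = logB.nrow(), n = logB.ncol();
  NumericMatrix d(T, n);
  IntegerMatrix bp(T, n);
  for (int i = 0; i < n; ++i) d(0, i) = logpi[i] + logB(0, i);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < n; ++j) {
      double best = d(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < n; ++i) {
        double v = d(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      d(t, j) = best + logB(t, j);
      bp(t, j) = arg;
    }
  int last = 0;
  double best = d(T - 1, 0);
  for (int i = 1; i < n; ++i)
    if (d(T - 1, i) > best) { best = d(T - 1, i); last = i; }
  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 1; t > 0; --t) path[t - 1] = bp(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R
  return List::create(_["path"] = path, _["logprob"] = best);
}
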