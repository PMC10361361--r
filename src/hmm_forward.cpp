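// Forward-algorithm likelihood and Viterbi decoding for the two-state
// time-inhomogeneous HMM. Observations are daily step lengths (gamma) and
// turning angles (wrapped Cauchy); NA observations are marginalized out
// (their emission log density is 0) while transitions still apply. The
// transition matrix applied on the move into day t is Gamma(t), supplied as
// per-day switch probabilities g12[day], g21[day] (1-based day index).
//
// Probabilities are renormalized at every step and the log normalizer
// accumulated, so T = 365 series cannot underflow.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix emission_logdens_cpp(NumericVector step, NumericVector turn,
                                   NumericVector shape, NumericVector rate,
                                   NumericVector mu, NumericVector rho) {
  const int n = step.size();
  NumericMatrix out(n, 2);
  double gconst[2], wconst[2], lrate[2];
  for (int s = 0; s < 2; ++s) {
    gconst[s] = shape[s] * std::log(rate[s]) - R::lgammafn(shape[s]);
    wconst[s] = std::log1p(-rho[s] * rho[s]) - std::log(2.0 * M_PI);
    lrate[s] = rate[s];
  }
  for (int i = 0; i < n; ++i) {
    const bool has_step = !NumericVector::is_na(step[i]);
    const bool has_turn = !NumericVector::is_na(turn[i]);
    const double ls = has_step ? std::log(step[i]) : 0.0;
    for (int s = 0; s < 2; ++s) {
      double ld = 0.0;
      if (has_step)
        ld += gconst[s] + (shape[s] - 1.0) * ls - lrate[s] * step[i];
      if (has_turn)
        ld += wconst[s] -
          std::log1p(rho[s] * rho[s] - 2.0 * rho[s] * std::cos(turn[i] - mu[s]));
      out(i, s) = ld;
    }
  }
  return out;
}

// series_start: 0-based offset of each series' first row in logdens;
// series_len: rows per series; start_day: biological day of the first row;
// phi1: P(state 1) on the first day, per series.
// [[Rcpp::export]]
NumericVector forward_cpp(NumericMatrix logdens, IntegerVector series_start,
                          IntegerVector series_len, IntegerVector start_day,
                          NumericVector phi1, NumericVector g12,
                          NumericVector g21) {
  const int ns = series_start.size();
  NumericVector ll(ns);
  for (int j = 0; j < ns; ++j) {
    const int off = series_start[j], len = series_len[j];
    double a1, a2, acc = 0.0;
    {
      const double m = std::max(logdens(off, 0), logdens(off, 1));
      if (m == R_NegInf) { ll[j] = R_NegInf; continue; }
      a1 = phi1[j] * std::exp(logdens(off, 0) - m);
      a2 = (1.0 - phi1[j]) * std::exp(logdens(off, 1) - m);
      const double s = a1 + a2;
      acc = m + std::log(s);
      a1 /= s; a2 /= s;
    }
    for (int t = 1; t < len; ++t) {
      const int day = start_day[j] + t;          // 1-based day of row t
      const double p12 = g12[day - 1], p21 = g21[day - 1];
      const double w1 = a1 * (1.0 - p12) + a2 * p21;
      const double w2 = a1 * p12 + a2 * (1.0 - p21);
      const int r = off + t;
      const double m = std::max(logdens(r, 0), logdens(r, 1));
      if (m == R_NegInf) { acc = R_NegInf; break; }
      const double u1 = w1 * std::exp(logdens(r, 0) - m);
      const double u2 = w2 * std::exp(logdens(r, 1) - m);
      const double s = u1 + u2;
      acc += m + std::log(s);
      a1 = u1 / s; a2 = u2 / s;
    }
    ll[j] = acc;
  }
  return ll;
}

// Most probable state path; ties broken toward state 1.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logdens, int start_day,
                          double phi1, NumericVector g12, NumericVector g21) {
  const int T = logdens.nrow();
  IntegerVector path(T);
  std::vector<double> d1(T), d2(T);
  std::vector<int> bp1(T), bp2(T);
  d1[0] = std::log(phi1) + logdens(0, 0);
  d2[0] = std::log1p(-phi1) + logdens(0, 1);
  for (int t = 1; t < T; ++t) {
    const int day = start_day + t;
    const double l11 = std::log1p(-g12[day - 1]), l12 = std::log(g12[day - 1]);
    const double l21 = std::log(g21[day - 1]), l22 = std::log1p(-g21[day - 1]);
    const double c11 = d1[t - 1] + l11, c21 = d2[t - 1] + l21;
    if (c11 >= c21) { d1[t] = c11; bp1[t] = 1; } else { d1[t] = c21; bp1[t] = 2; }
    const double c12 = d1[t - 1] + l12, c22 = d2[t - 1] + l22;
    if (c12 >= c22) { d2[t] = c12; bp2[t] = 1; } else { d2[t] = c22; bp2[t] = 2; }
    d1[t] += logdens(t, 0);
    d2[t] += logdens(t, 1);
  }
  path[T - 1] = (d1[T - 1] >= d2[T - 1]) ? 1 : 2;
  for (int t = T - 1; t > 0; --t)
    path[t - 1] = (path[t] == 1) ? bp1[t] : bp2[t];
  return path;
}
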