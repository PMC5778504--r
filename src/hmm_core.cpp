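#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one contiguous segment.
// logb: T x K matrix of (expected) log emission densities; rows with all
// zeros act as missing observations.  logpi, logA hold (expected) log
// initial and transition scores (not necessarily normalized: variational
// "tilde" parameters are sub-normalized).
// Returns per-frame posteriors gamma, summed transition counts xi,
// and the log normalizer.
// [[Rcpp::export(name = ".fb_segment")]]
List fb_segment(NumericMatrix logb, NumericVector logpi, NumericMatrix logA) {
  const int T = logb.nrow(), K = logb.ncol();
  NumericMatrix B(T, K);
  NumericVector bscale(T);
  for (int t = 0; t < T; ++t) {
    double m = logb(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logb(t, k));
    bscale[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logb(t, k) - m);
  }
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));
  NumericVector pi(K);
  for (int k = 0; k < K; ++k) pi[k] = std::exp(logpi[k]);

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double logZ = 0.0;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) stop("forward pass underflow at frame 0");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  logZ += std::log(s) + bscale[0];
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0) stop("forward pass underflow");
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
    logZ += std::log(s) + bscale[t];
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t - 1, i) * A(i, j) * B(t, j) * beta(t, j) / c[t];
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["logZ"] = logZ);
}

// Most probable state path (dynamic programming) for one segment.
// [[Rcpp::export(name = ".viterbi_segment")]]
IntegerVector viterbi_segment(NumericMatrix logb, NumericVector logpi,
                              NumericMatrix logA) {
  const int T = logb.nrow(), K = logb.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logb(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logb(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based state indices
}
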