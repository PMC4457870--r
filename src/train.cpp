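#include <Rcpp.h>
using namespace Rcpp;

// Online one-class perceptron learning with imbalanced plasticity.
//
// X is the K x N pattern matrix in its native coding.  The update signal is
// x_i - shift (shift = 0 for bipolar/zeromean, shift = f for 0/1 inputs, so
// that the signal is the zero-mean form in every coding).  The postsynaptic
// current is h = sum_i w_i x_i - fsum * sum_i w_i - thr; for the adaptive
// threshold model fsum = f (gamma = f*|w| + theta_f*sqrt(N)), otherwise 0.
//
// rule: 0 = stop-learning (no change once the pattern fires),
//       1 = decay variant (uniform depression -eps*lam when it fires).
// m counts plasticity events triggered by h < 0 only.
// Convergence is a separate no-plasticity probe over all K patterns at the
// end of each epoch; the decay variant is never applied during the probe.
// [[Rcpp::export(name = ".ocp_train_cpp")]]
List ocp_train_cpp(NumericMatrix X, double thr, double fsum, double shift,
                   double eps, double lam, int rule, int max_epochs,
                   NumericVector w0) {
  const int K = X.nrow(), N = X.ncol();
  NumericVector w = clone(w0);
  double m = 0.0;
  int epochs = 0;
  bool converged = false;

  for (int ep = 0; ep < max_epochs; ++ep) {
    IntegerVector ord = sample(K, K, false);  // R RNG, 1-based
    for (int kk = 0; kk < K; ++kk) {
      const int k = ord[kk] - 1;
      double dot = 0.0, sw = 0.0;
      for (int i = 0; i < N; ++i) { dot += w[i] * X(k, i); sw += w[i]; }
      const double h = dot - fsum * sw - thr;
      if (h < 0.0) {
        for (int i = 0; i < N; ++i) {
          const double wi = w[i] + eps * ((X(k, i) - shift) - lam);
          w[i] = wi > 0.0 ? wi : 0.0;
        }
        m += 1.0;
      } else if (rule == 1 && lam > 0.0) {
        for (int i = 0; i < N; ++i) {
          const double wi = w[i] - eps * lam;
          w[i] = wi > 0.0 ? wi : 0.0;
        }
      }
    }
    epochs = ep + 1;
    // no-plasticity convergence probe
    bool all_fire = true;
    double sw = 0.0;
    for (int i = 0; i < N; ++i) sw += w[i];
    for (int k = 0; k < K && all_fire; ++k) {
      double dot = 0.0;
      for (int i = 0; i < N; ++i) dot += w[i] * X(k, i);
      if (dot - fsum * sw - thr < 0.0) all_fire = false;
    }
    if (all_fire) { converged = true; break; }
  }

  return List::create(_["w"] = w, _["converged"] = converged,
                      _["epochs"] = epochs, _["updates"] = m);
}

// Krauth-Mezard min-over with rectification.  At every step the pattern with
// the smallest postsynaptic sum r_k = w.x^k is reinforced with the balanced
// rule (w += eps*x^k, then clamp at zero).  Iteration stops once the
// constraint min_k r_k >= thr holds and the normalised minimal stability
// min_k r_k/||w||_2 has not improved by more than stall_tol for stall_window
// consecutive steps (stall_window = 0: stop at first feasibility), or at
// max_iter.  Responses are maintained through the precomputed Gram matrix,
// with exact corrections for coordinates clamped at zero.
// [[Rcpp::export(name = ".minover_cpp")]]
List minover_cpp(NumericMatrix X, double thr, double eps, double max_iter,
                 int stall_window, double stall_tol) {
  const int K = X.nrow(), N = X.ncol();
  NumericVector w(N), r(K);
  NumericMatrix G(K, K);
  for (int k = 0; k < K; ++k)
    for (int l = k; l < K; ++l) {
      double g = 0.0;
      for (int i = 0; i < N; ++i) g += X(k, i) * X(l, i);
      G(k, l) = g; G(l, k) = g;
    }

  double w2 = 0.0;          // ||w||_2^2
  double best_stab = R_NegInf;
  double iter_of_best = 0.0, it = 0.0;
  bool converged = false;

  while (it < max_iter) {
    it += 1.0;
    int kmin = 0;
    for (int k = 1; k < K; ++k) if (r[k] < r[kmin]) kmin = k;

    // balanced update on the minimally stable pattern, with rectification;
    // r_k gains eps*G(kmin,k) plus a correction for every clamped coordinate
    for (int i = 0; i < N; ++i) {
      const double wold = w[i];
      double wnew = wold + eps * X(kmin, i);
      if (wnew < 0.0) {
        const double corr = -wnew;  // shortfall relative to the unclamped step
        wnew = 0.0;
        for (int k = 0; k < K; ++k) r[k] += corr * X(k, i);
      }
      w2 += wnew * wnew - wold * wold;
      w[i] = wnew;
    }
    for (int k = 0; k < K; ++k) r[k] += eps * G(kmin, k);

    if (w2 > 0.0) {
      double rmin = r[0];
      for (int k = 1; k < K; ++k) if (r[k] < rmin) rmin = r[k];
      const double stab = rmin / std::sqrt(w2);
      if (stab > best_stab + stall_tol) { best_stab = stab; iter_of_best = it; }
      if (rmin >= thr && it - iter_of_best >= stall_window) { converged = true; break; }
    }
  }

  return List::create(_["w"] = w, _["iterations"] = it,
                      _["converged"] = converged, _["min_stability"] = best_stab);
}
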