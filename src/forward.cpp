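#include <Rcpp.h>
using namespace Rcpp;

// Wavelet activation functions, keyed by integer code (see wavelet_codes in R).
// 1 = morlet, 2 = mexican_hat, 3 = gauss1, 4 = haar.
static inline double eval_wavelet(const int code, const double t) {
  switch (code) {
  case 1:
    return std::cos(5.0 * t) * std::exp(-0.5 * t * t);
  case 2:
    return (1.0 - t * t) * std::exp(-0.5 * t * t);
  case 3:
    return -t * std::exp(-0.5 * t * t);
  case 4:
    if (t >= 0.0 && t < 0.5) return 1.0;
    if (t >= 0.5 && t < 1.0) return -1.0;
    return 0.0;
  }
  return NA_REAL;
}

// Batch forward pass of a wavelet neural network over the rows of X.
//
// Each of the M wavelons has I input slots; slot n of wavelon m reads feature
// feat(n, m) (1-based).  For the active slots (sw == 1) the wavelet argument is
//   z_n = (w_n * x - beta_n) / max(alpha_n, alpha_min)
// and rotation couples consecutive active slots cyclically:
//   z'_n = z_n + R_n * z_{succ(n)}   (z' = z when only one slot is active).
// The wavelon response is the product of psi(z'_n) over active slots; silent
// wavelons (ot == 0, or no active slot) contribute 0.  The network output adds
// bias theta and the shortcut terms a_f * x_f.
// [[Rcpp::export]]
NumericVector wnn_forward_cpp(const NumericMatrix& X,
                              const IntegerMatrix& feat,
                              const IntegerMatrix& sw,
                              const NumericMatrix& w,
                              const NumericMatrix& alpha,
                              const NumericMatrix& beta,
                              const NumericMatrix& rot,
                              const IntegerVector& psi,
                              const NumericVector& wt,
                              const IntegerVector& ot,
                              const NumericVector& a,
                              const double theta,
                              const double alpha_min) {
  const int N = X.nrow();
  const int F = X.ncol();
  const int M = feat.ncol();
  const int I = feat.nrow();

  NumericVector out(N, theta);

  for (int f = 0; f < F; ++f) {
    const double af = a[f];
    if (af != 0.0) {
      for (int i = 0; i < N; ++i) out[i] += af * X(i, f);
    }
  }

  std::vector<int> act(I);
  std::vector<double> z(I);

  for (int m = 0; m < M; ++m) {
    if (ot[m] == 0) continue;
    int k = 0;
    for (int n = 0; n < I; ++n) {
      if (sw(n, m) == 1) act[k++] = n;
    }
    if (k == 0) continue;
    const int code = psi[m];
    const double wtm = wt[m];
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < k; ++j) {
        const int n = act[j];
        double al = alpha(n, m);
        if (al < alpha_min) al = alpha_min;
        z[j] = (w(n, m) * X(i, feat(n, m) - 1) - beta(n, m)) / al;
      }
      double prod = 1.0;
      if (k == 1) {
        prod = eval_wavelet(code, z[0]);
      } else {
        for (int j = 0; j < k; ++j) {
          prod *= eval_wavelet(code, z[j] + rot(act[j], m) * z[(j + 1) % k]);
        }
      }
      out[i] += wtm * prod;
    }
  }
  return out;
}
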