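#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Choi-Williams ambiguity-domain kernel exp(-(2*pi*theta*tau)^2 / sigma),
// theta in cycles/sample (FFT-wrapped), tau in samples (FFT-wrapped).
// Laid out to match the (theta, tau) layout of fft(K) where K is t x tau.
// [[Rcpp::export]]
arma::mat cw_kernel_cpp(int n, double sigma) {
  vec theta(n), tau(n);
  for (int m = 0; m < n; ++m)
    theta(m) = ((m < n / 2) ? m : m - n) / (double)n;
  for (int j = 0; j < n; ++j)
    tau(j) = (j < n / 2) ? j : j - n;
  mat phi = exp(-square(2.0 * M_PI * theta * tau.t()) / sigma);
  return phi;
}

// Discrete Wigner-Ville distribution of an analytic frame x (length n),
// optionally smoothed in the ambiguity domain by the Choi-Williams kernel.
// Instantaneous autocorrelation K(t, tau) = x(t + tau) * conj(x(t - tau))
// (lags truncated at the frame edges); the FFT over tau yields n frequency
// bins spaced fs / (2 n), i.e. spanning [0, fs/2).
// Returns an n x n real matrix, rows = frequency bins, cols = time samples.
// [[Rcpp::export]]
arma::mat cwd_frame_cpp(const arma::cx_vec& x, double sigma, bool smooth,
                        Rcpp::Nullable<Rcpp::NumericMatrix> kernel =
                            R_NilValue) {
  const int n = x.n_elem;
  const cx_double* px = x.memptr();
  cx_mat K(n, n, fill::zeros); // rows t, cols wrapped lag index
  for (int j = 0; j < n; ++j) {
    int tau = (j < n / 2) ? j : j - n;
    int a = std::abs(tau), b = n - 1 - std::abs(tau);
    cx_double* col = K.colptr(j);
    for (int t = a; t <= b; ++t)
      col[t] = px[t + tau] * std::conj(px[t - tau]);
  }
  if (smooth) {
    cx_mat A = fft(K); // FFT over t: ambiguity function A(theta, tau)
    mat phi;
    if (kernel.isNotNull())
      phi = Rcpp::as<mat>(kernel.get());
    else
      phi = cw_kernel_cpp(n, sigma);
    cx_double* pa = A.memptr();
    const double* pp = phi.memptr();
    const size_t nn = (size_t)n * n;
    for (size_t i = 0; i < nn; ++i) pa[i] *= pp[i];
    K = ifft(A);
  }
  // FFT over tau (rows of K): transpose without conjugation first
  cx_mat W = fft(K.st()); // rows = frequency bin, cols = time
  return real(W);
}
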