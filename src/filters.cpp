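#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with zero initial conditions,
// applied down the rows of x (one series per column).
static void lfilter_inplace(const std::vector<double>& b,
                            const std::vector<double>& a,
                            std::vector<double>& x, int n, int ncol) {
  const int nb = (int)b.size(), na = (int)a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz);
  for (int j = 0; j < ncol; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    double* col = x.data() + (size_t)j * n;
    for (int t = 0; t < n; ++t) {
      const double xt = col[t];
      const double yt = b[0] * xt + z[0];
      for (int k = 0; k < nz - 1; ++k) {
        const double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
        const double ak = (k + 1 < na) ? a[k + 1] : 0.0;
        z[k] = bk * xt + z[k + 1] - ak * yt;
      }
      const double bl = (nz < nb) ? b[nz] : 0.0;
      const double al = (nz < na) ? a[nz] : 0.0;
      z[nz - 1] = bl * xt - al * yt;
      col[t] = yt;
    }
  }
}

// Zero-phase forward-backward filtering with odd-symmetric edge extension
// of length 3*max(length(a), length(b)) at both ends (scipy-style padding,
// zero initial filter state). x: samples x series matrix; returns same shape.
// [[Rcpp::export(name = ".filtfilt_cpp")]]
NumericMatrix filtfilt_cpp(NumericVector b, NumericVector a, NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  const std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  const int pad = 3 * (int)std::max(bv.size(), av.size());
  if (n <= pad)
    stop("signal too short for zero-phase filtering: need more than %d samples, got %d",
         pad, n);
  const int ne = n + 2 * pad;
  std::vector<double> ext((size_t)ne * m);
  for (int j = 0; j < m; ++j) {
    double* col = ext.data() + (size_t)j * ne;
    const double x0 = x(0, j), xn = x(n - 1, j);
    for (int t = 0; t < pad; ++t) col[t] = 2.0 * x0 - x(pad - t, j);
    for (int t = 0; t < n; ++t) col[pad + t] = x(t, j);
    for (int t = 0; t < pad; ++t) col[pad + n + t] = 2.0 * xn - x(n - 2 - t, j);
  }
  lfilter_inplace(bv, av, ext, ne, m);
  for (int j = 0; j < m; ++j) {  // reverse each column
    double* col = ext.data() + (size_t)j * ne;
    std::reverse(col, col + ne);
  }
  lfilter_inplace(bv, av, ext, ne, m);
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double* col = ext.data() + (size_t)j * ne;
    // output is still reversed: original sample t sits at ne - 1 - (pad + t)
    for (int t = 0; t < n; ++t) out(t, j) = col[ne - 1 - pad - t];
  }
  return out;
}

// Per-trial channel covariances from a samples-major matrix (samples x
// (trials*channels), column (c*n + i) holding trial i of channel c), over
// the half-open sample window [s0, s1); biased 1/T, means removed.
// [[Rcpp::export(name = ".window_cov_sm_cpp")]]
NumericMatrix window_cov_sm_cpp(NumericMatrix x, int n, int M, int s0, int s1) {
  if ((size_t)n * M != (size_t)x.ncol()) stop("layout mismatch");
  if (s0 < 0 || s1 > x.nrow() || s1 <= s0) stop("sample window out of range");
  const int L = s1 - s0;
  NumericMatrix out(n, M * M);
  std::vector<double> X((size_t)M * L);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < M; ++c) {
      const double* col = &x(0, c * n + i);
      double s = 0.0;
      for (int t = 0; t < L; ++t) { X[(size_t)c * L + t] = col[s0 + t]; s += col[s0 + t]; }
      const double mu = s / L;
      for (int t = 0; t < L; ++t) X[(size_t)c * L + t] -= mu;
    }
    for (int c1 = 0; c1 < M; ++c1) {
      const double* a1 = X.data() + (size_t)c1 * L;
      for (int c2 = c1; c2 < M; ++c2) {
        const double* a2 = X.data() + (size_t)c2 * L;
        double s = 0.0;
        for (int t = 0; t < L; ++t) s += a1[t] * a2[t];
        s /= L;
        out(i, c1 * M + c2) = s;
        out(i, c2 * M + c1) = s;
      }
    }
  }
  return out;
}

// Per-trial channel covariance matrices of a trials x channels x samples
// array restricted to the half-open sample window [s0, s1) (0-based), with
// per-channel window means removed and the biased 1/T normalization.
// Returns trials x (channels^2) matrix of vectorized covariances.
// [[Rcpp::export(name = ".window_cov_cpp")]]
NumericMatrix window_cov_cpp(NumericVector arr, int s0, int s1) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("expected a 3-d array");
  const int n = dims[0], M = dims[1], S = dims[2];
  if (s0 < 0 || s1 > S || s1 <= s0) stop("sample window out of range");
  const int L = s1 - s0;
  NumericMatrix out(n, M * M);
  std::vector<double> X((size_t)M * L), mu(M);
  const double* A = arr.begin();
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < M; ++c) {
      double s = 0.0;
      for (int t = 0; t < L; ++t) {
        const double v = A[(size_t)(s0 + t) * n * M + (size_t)c * n + i];
        X[(size_t)c * L + t] = v;
        s += v;
      }
      mu[c] = s / L;
      for (int t = 0; t < L; ++t) X[(size_t)c * L + t] -= mu[c];
    }
    for (int c1 = 0; c1 < M; ++c1) {
      const double* a1 = X.data() + (size_t)c1 * L;
      for (int c2 = c1; c2 < M; ++c2) {
        const double* a2 = X.data() + (size_t)c2 * L;
        double s = 0.0;
        for (int t = 0; t < L; ++t) s += a1[t] * a2[t];
        s /= L;
        out(i, c1 * M + c2) = s;
        out(i, c2 * M + c1) = s;
      }
    }
  }
  return out;
}
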