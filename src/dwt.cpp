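// Decimated 1-D analysis/synthesis filtering along matrix columns, the inner
// kernels of the 2-D wavelet transform. Symmetric (half-point) boundary
// extension, convolution, downsampling by two with offset two; synthesis
// upsamples, filters with the reconstruction pair, and crops the boundary
// surplus. All in double precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// half-point symmetric reflection of signal index e into [0, n)
static inline int reflect_idx(int e, int n) {
  if (e < 0) {
    e = -e - 1;
    if (e > n - 1) e = n - 1;   // clamp for signals shorter than the filter
  } else if (e >= n) {
    e = 2 * n - e - 1;
    if (e < 0) e = 0;
  }
  return e;
}

// analysis: out[k] = sum_j f[j] * x_ext[2k + 1 - j], k = 0 .. (n+p-1)/2 - 1
// [[Rcpp::export]]
arma::mat cpp_dwt_rows(const arma::mat& x, const arma::vec& f) {
  const int n = x.n_rows, m = x.n_cols, p = f.n_elem;
  const int no = (n + p - 1) / 2;
  mat out(no, m);
  for (int c = 0; c < m; ++c) {
    const double* xc = x.colptr(c);
    double* oc = out.colptr(c);
    for (int k = 0; k < no; ++k) {
      double acc = 0.0;
      const int base = 2 * k + 1;
      for (int j = 0; j < p; ++j) {
        acc += f[j] * xc[reflect_idx(base - j, n)];
      }
      oc[k] = acc;
    }
  }
  return out;
}

// synthesis: upsampled coefficients (a at even 0-based positions of a length
// 2c vector), full convolution with the reconstruction pair, crop p-2 from
// the left, emit n_out rows
// [[Rcpp::export]]
arma::mat cpp_idwt_rows(const arma::mat& a, const arma::mat& d,
                        const arma::vec& lo, const arma::vec& hi, int n_out) {
  const int cc = a.n_rows, m = a.n_cols, p = lo.n_elem;
  mat out(n_out, m);
  for (int c = 0; c < m; ++c) {
    const double* ac = a.colptr(c);
    const double* dc = d.colptr(c);
    double* oc = out.colptr(c);
    for (int o = 0; o < n_out; ++o) {
      double acc = 0.0;
      for (int j = 0; j < p; ++j) {
        const int u1 = o + p - 1 - j;        // 1-based upsampled index
        if (u1 < 1 || u1 > 2 * cc || (u1 % 2) == 0) continue;
        const int idx = (u1 - 1) / 2;
        acc += lo[j] * ac[idx] + hi[j] * dc[idx];
      }
      oc[o] = acc;
    }
  }
  return out;
}
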