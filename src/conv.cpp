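#include <Rcpp.h>
using namespace Rcpp;

// Reflect an out-of-range index into [0, n) with half-sample symmetric
// boundary handling (..., x1, x0 | x0, x1, ..., x_{n-1} | x_{n-1}, ...).
static inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Core of the undecimated axis correlation; `arr` and `out` are full-grid
// buffers in R column-major order:
//   out[i] = sum_t taps[t] * in[reflect(i + t - offset)]
static void axis_convolve_core(const double* arr, double* out,
                               const int* dims, int axis,
                               const double* taps, int L, int offset) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sx = 1, sy = nx, sz = nx * ny;
  int stride, n_line, su, sv, nu, nv;
  if (axis == 0)      { stride = sx; n_line = nx; su = sy; sv = sz; nu = ny; nv = nz; }
  else if (axis == 1) { stride = sy; n_line = ny; su = sx; sv = sz; nu = nx; nv = nz; }
  else                { stride = sz; n_line = nz; su = sx; sv = sy; nu = nx; nv = ny; }

  std::vector<double> line(n_line);
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      const long base = (long)u * su + (long)v * sv;
      for (int i = 0; i < n_line; ++i) line[i] = arr[base + (long)i * stride];
      const int lo = std::max(0, offset);
      const int hi = std::min(n_line, n_line - (L - 1 - offset));
      for (int i = lo; i < hi; ++i) { // interior: no boundary reflection
        double acc = 0.0;
        const double* seg = &line[i - offset];
        for (int t = 0; t < L; ++t) acc += taps[t] * seg[t];
        out[base + (long)i * stride] = acc;
      }
      for (int i = 0; i < n_line; ++i) {
        if (i >= lo && i < hi) continue;
        double acc = 0.0;
        for (int t = 0; t < L; ++t) {
          acc += taps[t] * line[reflect_index(i + t - offset, n_line)];
        }
        out[base + (long)i * stride] = acc;
      }
    }
  }
}

// Undecimated correlation of a 3D array with a short filter along one axis,
// keeping the grid size.
// [[Rcpp::export]]
NumericVector cpp_axis_convolve(const NumericVector& arr,
                                const IntegerVector& dims,
                                int axis,
                                const NumericVector& taps,
                                int offset) {
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  if (dims[axis] < taps.size()) {
    stop("array extent along axis is smaller than the filter");
  }
  NumericVector out(arr.size());
  axis_convolve_core(arr.begin(), out.begin(), dims.begin(), axis,
                     taps.begin(), taps.size(), offset);
  return out;
}

// All 8 single-level undecimated wavelet subbands in one call, via the
// separable filter tree (x, then y, then z). Columns of the returned
// matrix are LLL, HLL, LHL, HHL, LLH, HLH, LHH, HHH (letter 1 = x filter).
// [[Rcpp::export]]
NumericMatrix cpp_wavelet8(const NumericVector& arr,
                           const IntegerVector& dims,
                           const NumericVector& lo,
                           const NumericVector& hi,
                           int offset) {
  const int L = lo.size();
  for (int a = 0; a < 3; ++a) {
    if (dims[a] < L) stop("volume too small for the filter support");
  }
  const R_xlen_t n = arr.size();
  NumericMatrix out(n, 8);
  std::vector<double> bx(2 * n), bxy(4 * n);
  const double* taps[2] = { lo.begin(), hi.begin() };
  for (int fx = 0; fx < 2; ++fx) {
    axis_convolve_core(arr.begin(), &bx[(size_t)fx * n], dims.begin(), 0,
                       taps[fx], L, offset);
  }
  for (int fx = 0; fx < 2; ++fx) {
    for (int fy = 0; fy < 2; ++fy) {
      axis_convolve_core(&bx[(size_t)fx * n], &bxy[(size_t)(fy * 2 + fx) * n],
                         dims.begin(), 1, taps[fy], L, offset);
    }
  }
  for (int fz = 0; fz < 2; ++fz) {
    for (int fy = 0; fy < 2; ++fy) {
      for (int fx = 0; fx < 2; ++fx) {
        const int col = fz * 4 + fy * 2 + fx;
        axis_convolve_core(&bxy[(size_t)(fy * 2 + fx) * n],
                           &out(0, col), dims.begin(), 2, taps[fz], L, offset);
      }
    }
  }
  return out;
}
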