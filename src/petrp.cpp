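#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3-D logical array with an arbitrary
// neighbourhood (offsets given as an n x 3 integer matrix, e.g. the 6- or
// 26-neighbourhood).  Returns an integer array: 0 = background, components
// numbered from 1 in discovery order.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim,
                           IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int noff = offsets.nrow();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int r = (int)(v % ((R_xlen_t)nx * ny));
      int j = r / nx, i = r % nx;
      for (int o = 0; o < noff; ++o) {
        int ii = i + offsets(o, 0);
        int jj = j + offsets(o, 1);
        int kk = k + offsets(o, 2);
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Separable 1-D convolution along one axis of a 3-D array with edge
// renormalisation (kernel mass falling outside the grid is redistributed),
// so a constant field is invariant under blurring.
// [[Rcpp::export(name = ".convolve_axis_cpp")]]
NumericVector convolve_axis_cpp(NumericVector arr, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kn = kernel.size();
  const int kh = kn / 2;  // kernel assumed odd-length, centred
  NumericVector out((R_xlen_t)nx * ny * nz);
  const int nax = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  // strides
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t sa = (axis == 1) ? sx : (axis == 2) ? sy : sz;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int a = (axis == 1) ? i : (axis == 2) ? j : k;
        R_xlen_t idx = (R_xlen_t)k * sz + (R_xlen_t)j * sy + i;
        double acc = 0.0, wsum = 0.0;
        for (int t = -kh; t <= kh; ++t) {
          int aa = a + t;
          if (aa < 0 || aa >= nax) continue;
          double w = kernel[t + kh];
          acc += w * arr[idx + (R_xlen_t)t * sa];
          wsum += w;
        }
        out[idx] = (wsum > 0) ? acc / wsum : 0.0;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
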