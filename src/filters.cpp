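#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// NaN-aware median of the values collected in buf[0..n)
static double buf_median(std::vector<double> &buf) {
  if (buf.empty()) return NA_REAL;
  size_t n = buf.size();
  size_t mid = n / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
  double hi = buf[mid];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + mid);
  return 0.5 * (lo + hi);
}

// 2-D median filter for layer-by-sector matrices.
// Rows (layers, base->apex) are edge-replicated; columns (angular sectors)
// wrap circularly because the anterior cut of the myocardial ring is
// arbitrary.  NaN entries (empty compartments) are excluded from each
// window; an all-NaN window stays NaN.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix x, int kernel) {
  if (kernel < 1 || kernel % 2 == 0)
    stop("kernel must be an odd positive integer");
  int nr = x.nrow(), nc = x.ncol(), h = kernel / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)kernel * kernel);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int jj = (j + dj) % nc;
        if (jj < 0) jj += nc;                 // circular wrap along sectors
        for (int di = -h; di <= h; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0;                 // replicate along layers
          if (ii >= nr) ii = nr - 1;
          double v = x(ii, jj);
          if (!ISNAN(v)) buf.push_back(v);
        }
      }
      out(i, j) = buf_median(buf);
    }
  }
  return out;
}

// 6-connected component labelling of a 3-D logical mask (first-order
// neighbours along each axis).  Returns an integer array of the same
// dimensions with 0 for background and 1..k for components.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] == TRUE && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
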