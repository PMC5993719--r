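// Largest 6-connected foreground component of a 3D logical mask.
// Optional cleanup for noisy stacks before convex-hull extraction.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".largest_component6")]]
LogicalVector largest_component6(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<int> label(n, 0);
  int ncomp = 0;
  R_xlen_t best_size = 0;
  int best_label = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.push_back(s);
    label[s] = ncomp;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((R_xlen_t)nz * ny);
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t idx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[idx] && !label[idx]) {
          label[idx] = ncomp;
          stack.push_back(idx);
        }
      }
    }
    if (size > best_size) { best_size = size; best_label = ncomp; }
  }

  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (label[s] == best_label);
  return out;
}
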