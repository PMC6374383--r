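#include <Rcpp.h>
#include <vector>

// 3-D connected-component labeling with 26-connectivity.
// mask: logical/integer vector in (z, y, x) array layout, dims = c(nz, ny, nx)
// (column-major, z fastest). Returns an integer vector of the same layout with
// background 0 and components labeled 1..n in scan order.
// Iterative flood fill (explicit stack) to avoid recursion-depth limits.

// [[Rcpp::export(name = ".label_cc_3d")]]
Rcpp::IntegerVector label_cc_3d(Rcpp::LogicalVector mask,
                                Rcpp::IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) Rcpp::stop("mask length does not match dims");
  Rcpp::IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  auto idx = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
  };

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx(z, y, x);
        if (!mask[i] || labels[i] != 0) continue;
        ++next_label;
        labels[i] = next_label;
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx;
            if (xx < 0 || xx >= nx) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int yy = cy + dy;
              if (yy < 0 || yy >= ny) continue;
              for (int dz = -1; dz <= 1; ++dz) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int zz = cz + dz;
                if (zz < 0 || zz >= nz) continue;
                R_xlen_t j = idx(zz, yy, xx);
                if (mask[j] && labels[j] == 0) {
                  labels[j] = next_label;
                  stack.push_back(j);
                }
              }
            }
          }
        }
      }
  return labels;
}
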