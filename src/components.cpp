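#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D connected-component labeling of a logical mask by breadth-first
// search. Connectivity 6 (faces), 18 (faces+edges) or 26 (full Moore
// neighborhood). Labels are 1..n_components in discovery order; background
// stays 0.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  if (dims.size() != 3)
    stop("`dims` must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n)
    stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }

  IntegerVector labels(n, 0);
  int current = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          q.push(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n_components") = current;
  return labels;
}
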