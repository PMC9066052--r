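#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Flood-fill labeling of a 3D logical array. Connectivity 6 (faces) or 26
// (faces+edges+corners). Labels are assigned in raster-scan order of the
// first-encountered voxel, so the result is deterministic and labels are
// contiguous from 1.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int ord = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nneigh = (int)dx.size();

  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nneigh; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          q.push(j);
        }
      }
    }
  }
  return labels;
}
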