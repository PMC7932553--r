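#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// Label connected components of a logical 2D or 3D array.
// 2D uses 8-connectivity; 3D uses 26-connectivity.  Labels are assigned
// in raster-scan order of each component's first voxel, starting at 1.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3)
    stop("mask must be 2D or 3D");
  const int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("dims do not match mask length");

  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  // Scan: union each foreground voxel with already-visited neighbours
  // (half of the 8/26-neighbourhood suffices).
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (!mask[i]) continue;
        for (int dz = -1; dz <= 0; ++dz) {
          int zz = z + dz;
          if (zz < 0) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              // only strictly-earlier voxels in scan order
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
              int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
              if (mask[j]) uf_union(parent, (int)j, (int)i);
            }
          }
        }
      }
    }
  }

  IntegerVector out(n, 0);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, (int)i);
    if (relabel[r] == 0) relabel[r] = ++next;
    out[i] = relabel[r];
  }
  out.attr("dim") = dims;
  return out;
}
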