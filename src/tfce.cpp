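#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path halving; sizes tracked at roots.
static inline int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement on a 3D statistic volume.
//
// TFCE(v) = sum over h = dh, 2dh, ..., <= stat(v) of e(h,v)^E * h^H * dh,
// where e(h,v) is the size of the connected component containing v among
// voxels with stat >= h (6/18/26 neighbourhood). Computed by sweeping the
// thresholds from the top and growing components incrementally with a
// union-find, so the cost is O(n_steps * n_active) rather than a fresh
// labelling per threshold. Voxels with stat <= 0 (or outside the mask)
// score 0 and never join a component.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       LogicalVector mask, double E, double H,
                       double dh, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (stat.size() != n || mask.size() != n)
    stop("stat/mask length does not match dims");
  if (!(connectivity == 6 || connectivity == 18 || connectivity == 26))
    stop("connectivity must be 6, 18 or 26");
  if (dh <= 0) stop("dh must be positive");

  NumericVector out(n);

  // neighbour offsets for the requested connectivity
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  // voxels eligible for enhancement: in-mask, positive, finite checked in R
  std::vector<int> vox;
  vox.reserve(n / 4);
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (mask[i] && stat[i] > 0) {
      vox.push_back(i);
      if (stat[i] > hmax) hmax = stat[i];
    }
  }
  if (vox.empty()) return out;

  int nsteps = (int)std::floor(hmax / dh + 1e-12);
  if (nsteps < 1) return out;

  // sort eligible voxels by decreasing stat so each threshold sweep
  // activates a contiguous run
  std::sort(vox.begin(), vox.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  std::vector<int> activated;
  activated.reserve(vox.size());
  size_t next = 0;

  for (int k = nsteps; k >= 1; --k) {
    double h = dh * k;
    // activate voxels with stat >= h
    while (next < vox.size() && stat[vox[next]] >= h) {
      int i = vox[next++];
      parent[i] = i; csize[i] = 1; active[i] = 1;
      activated.push_back(i);
      int z = i / (nx * ny), rem = i % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (size_t m = 0; m < dxs.size(); ++m) {
        int xx = x + dxs[m], yy = y + dys[m], zz = z + dzs[m];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = xx + nx * (yy + ny * zz);
        if (!active[j]) continue;
        int ri = uf_find(parent, i), rj = uf_find(parent, j);
        if (ri != rj) { // union by size
          if (csize[ri] < csize[rj]) std::swap(ri, rj);
          parent[rj] = ri;
          csize[ri] += csize[rj];
        }
      }
    }
    // accumulate this threshold's contribution for every active voxel
    double hH = std::pow(h, H) * dh;
    for (size_t m = 0; m < activated.size(); ++m) {
      int i = activated[m];
      out[i] += std::pow((double)csize[uf_find(parent, i)], E) * hH;
    }
  }
  return out;
}
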