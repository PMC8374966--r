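#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cstdlib>
using namespace Rcpp;

// Offsets for 6/18/26 neighbourhoods on a 3D lattice.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

static void bfs_label(const int *mask, int *labels, int nx, int ny, int nz,
                      const std::vector<std::array<int, 3>> &off,
                      std::vector<int> &queue) {
  int next = 0;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++next;
    labels[s] = next;
    queue.clear();
    queue.push_back((int)s);
    while (!queue.empty()) {
      int cur = queue.back();
      queue.pop_back();
      int x = cur % nx;
      int y = (cur / nx) % ny;
      int z = cur / (nx * ny);
      for (const auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int idx = xx + nx * (yy + ny * zz);
        if (mask[idx] && !labels[idx]) {
          labels[idx] = next;
          queue.push_back(idx);
        }
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector labels((R_xlen_t)nx * ny * nz);
  auto off = neighbour_offsets(connectivity);
  std::vector<int> queue;
  bfs_label(LOGICAL(mask), INTEGER(labels), nx, ny, nz, off, queue);
  return labels;
}

// Per-permutation maxima of the cluster summaries used by the sign-flip
// null distribution. `excess` holds one permutation per row (flips x
// voxels); a voxel is supra-threshold where its excess statistic is > 0.
// Returns, per flip, the maximum cluster extent (voxels) and the maximum
// cluster mass (sum of excess over the cluster).
// [[Rcpp::export]]
List cluster_null_cpp(NumericMatrix excess, IntegerVector dim,
                      int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (excess.ncol() != nvox) stop("excess columns do not match volume size");
  int nperm = excess.nrow();
  IntegerVector max_size(nperm);
  NumericVector max_mass(nperm);
  auto off = neighbour_offsets(connectivity);
  std::vector<int> labels(nvox), queue, maskcol(nvox);
  std::vector<double> buf(nvox);
  for (int p = 0; p < nperm; ++p) {
    for (R_xlen_t v = 0; v < nvox; ++v) {
      buf[v] = excess(p, v);
      maskcol[v] = buf[v] > 0 ? 1 : 0;
    }
    std::fill(labels.begin(), labels.end(), 0);
    bfs_label(maskcol.data(), labels.data(), nx, ny, nz, off, queue);
    int nlab = 0;
    for (R_xlen_t i = 0; i < nvox; ++i) nlab = std::max(nlab, labels[i]);
    int best_size = 0;
    double best_mass = 0.0;
    if (nlab > 0) {
      std::vector<int> sizes(nlab, 0);
      std::vector<double> masses(nlab, 0.0);
      for (R_xlen_t i = 0; i < nvox; ++i)
        if (labels[i]) {
          ++sizes[labels[i] - 1];
          masses[labels[i] - 1] += buf[i];
        }
      best_size = *std::max_element(sizes.begin(), sizes.end());
      best_mass = *std::max_element(masses.begin(), masses.end());
    }
    max_size[p] = best_size;
    max_mass[p] = best_mass;
  }
  return List::create(Named("max_size") = max_size,
                      Named("max_mass") = max_mass);
}
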