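#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Convolve a 3D volume (R array layout, first index fastest) with a symmetric
// 1D kernel along one axis (1 = x, 2 = y, 3 = z). Edge-replicating padding:
// constant volumes stay constant and an interior impulse conserves its mass
// under a normalized kernel.
// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis(NumericVector vol, IntegerVector dim, int axis,
                        NumericVector kernel) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != vol.size()) stop("dim does not match volume length");
  const int kh = (kernel.size() - 1) / 2;
  if (kernel.size() != 2 * kh + 1) stop("kernel length must be odd");
  NumericVector out(vol.size());
  const double *v = vol.begin();
  const double *k = kernel.begin();
  double *o = out.begin();

  int n = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  // stride along the convolved axis
  R_xlen_t stride = (axis == 1) ? 1 : (axis == 2) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
  // iterate over all 1D lines along the axis
  R_xlen_t n_other = (R_xlen_t)nx * ny * nz / n;
  for (R_xlen_t line = 0; line < n_other; ++line) {
    // base index of this line
    R_xlen_t base;
    if (axis == 1) {
      base = line * nx;
    } else if (axis == 2) {
      R_xlen_t ix = line % nx, iz = line / nx;
      base = ix + (R_xlen_t)nx * ny * iz;
    } else {
      base = line;
    }
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int t = -kh; t <= kh; ++t) {
        int j = i + t;
        if (j < 0) j = 0; else if (j >= n) j = n - 1;
        acc += v[base + (R_xlen_t)j * stride] * k[kh + t];
      }
      o[base + (R_xlen_t)i * stride] = acc;
    }
  }
  return out;
}

// Label connected components of a 3D logical mask. connectivity 6 or 26.
// Labels are assigned in raster-scan order of each component's first voxel,
// so labeling is deterministic. Returns integer vector (0 = background).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim,
                               int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (nvox != mask.size()) stop("dim does not match mask length");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<std::array<int,3>> neigh;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        neigh.push_back({dx, dy, dz});
      }

  IntegerVector labels(nvox, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++cur;
    labels[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int px = p % nx, py = (p / nx) % ny, pz = p / ((R_xlen_t)nx * ny);
      for (size_t q = 0; q < neigh.size(); ++q) {
        int qx = px + neigh[q][0], qy = py + neigh[q][1], qz = pz + neigh[q][2];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
          continue;
        R_xlen_t qi = qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
        if (mask[qi] && labels[qi] == 0) {
          labels[qi] = cur;
          stack.push_back(qi);
        }
      }
    }
  }
  return labels;
}

// ---- kd-tree nearest neighbour between point sets ------------------------
// Exact 3D nearest neighbour with deterministic tie-breaking: among reference
// points at exactly equal squared distance, the smallest original index wins.

struct KDNode {
  int idx;        // index into the points array (original row)
  int left, right;
  int dimn;
};

struct KDTree {
  const double *pts; // m x 3, column-major (x then y then z blocks)
  int m;
  std::vector<KDNode> nodes;
  std::vector<int> order;

  double coord(int i, int d) const { return pts[i + (R_xlen_t)m * d]; }

  int build(int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int d = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(order.begin() + lo, order.begin() + mid, order.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, d), cb = coord(b, d);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    KDNode node;
    node.idx = order[mid];
    node.dimn = d;
    int self = (int)nodes.size();
    nodes.push_back(node);
    int l = build(lo, mid, depth + 1);
    int r = build(mid + 1, hi, depth + 1);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  void search(int node, double qx, double qy, double qz,
              double &bestD2, int &bestIdx) const {
    if (node < 0) return;
    const KDNode &nd = nodes[node];
    double dx = qx - coord(nd.idx, 0);
    double dy = qy - coord(nd.idx, 1);
    double dz = qz - coord(nd.idx, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestD2 || (d2 == bestD2 && nd.idx < bestIdx)) {
      bestD2 = d2;
      bestIdx = nd.idx;
    }
    double q[3] = {qx, qy, qz};
    double diff = q[nd.dimn] - coord(nd.idx, nd.dimn);
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search(near, qx, qy, qz, bestD2, bestIdx);
    if (diff * diff <= bestD2)  // <= so exact ties across the split are visited
      search(far, qx, qy, qz, bestD2, bestIdx);
  }
};

// [[Rcpp::export(name = ".nn_points")]]
List nn_points(NumericMatrix query, NumericMatrix ref) {
  if (query.ncol() != 3 || ref.ncol() != 3) stop("points must be n x 3");
  int n = query.nrow(), m = ref.nrow();
  if (m < 1) stop("reference set is empty");
  KDTree tree;
  tree.pts = ref.begin();
  tree.m = m;
  tree.order.resize(m);
  for (int i = 0; i < m; ++i) tree.order[i] = i;
  tree.nodes.reserve(m);
  int root = tree.build(0, m, 0);

  IntegerVector nn(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double bestD2 = R_PosInf;
    int bestIdx = m;
    tree.search(root, query(i, 0), query(i, 1), query(i, 2), bestD2, bestIdx);
    nn[i] = bestIdx + 1;  // 1-based for R
    dist[i] = std::sqrt(bestD2);
  }
  return List::create(_["index"] = nn, _["distance"] = dist);
}

// Exact nearest mask-voxel-center distance for off-grid query points, with
// anisotropic voxel sizes. Exhaustive over mask voxels; ties resolved to the
// smallest linear voxel index. Returns physical distances plus the 1-based
// linear index of the nearest voxel.
// [[Rcpp::export(name = ".nn_points_to_mask")]]
List nn_points_to_mask(NumericMatrix query, LogicalVector mask,
                       IntegerVector dim, NumericVector voxel_size) {
  if (query.ncol() != 3) stop("points must be n x 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double vx = voxel_size[0], vy = voxel_size[1], vz = voxel_size[2];
  std::vector<R_xlen_t> idx;
  std::vector<double> cx, cy, cz;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s]) continue;
    int px = s % nx, py = (s / nx) % ny, pz = s / ((R_xlen_t)nx * ny);
    idx.push_back(s);
    cx.push_back((px + 0.5) * vx);
    cy.push_back((py + 0.5) * vy);
    cz.push_back((pz + 0.5) * vz);
  }
  if (idx.empty()) stop("mask has no foreground voxels");
  int n = query.nrow();
  NumericVector dist(n);
  NumericVector nearest(n);
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double bestD2 = R_PosInf;
    R_xlen_t bestS = -1;
    for (size_t j = 0; j < idx.size(); ++j) {
      double dx = qx - cx[j], dy = qy - cy[j], dz = qz - cz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bestD2) { bestD2 = d2; bestS = idx[j]; }
    }
    dist[i] = std::sqrt(bestD2);
    nearest[i] = (double)(bestS + 1);
  }
  return List::create(_["index"] = nearest, _["distance"] = dist);
}
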