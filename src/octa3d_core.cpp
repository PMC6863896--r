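#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat <-> coordinate indexing follows R's column-major layout: for a
// volume of dim (n1, n2, n3), flat = i1 + n1 * (i2 + n2 * i3), 0-based.

static inline int flat3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// Label connected components of a 3D logical mask.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// Returns an integer array (flat) with 0 = background, 1..K = component id.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> d1, d2, d3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        d1.push_back(a); d2.push_back(b); d3.push_back(c);
      }
  const int nd = (int)d1.size();

  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int f = flat3(i, j, k, n1, n2);
        if (!mask[f] || lab[f]) continue;
        ++next;
        lab[f] = next;
        stack.clear();
        stack.push_back(f);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int ci = cur % n1, rem = cur / n1;
          int cj = rem % n2, ck = rem / n2;
          for (int q = 0; q < nd; ++q) {
            int ni = ci + d1[q], nj = cj + d2[q], nk = ck + d3[q];
            if (ni < 0 || ni >= n1 || nj < 0 || nj >= n2 || nk < 0 || nk >= n3) continue;
            int nf = flat3(ni, nj, nk, n1, n2);
            if (mask[nf] && !lab[nf]) { lab[nf] = next; stack.push_back(nf); }
          }
        }
      }
  return lab;
}

// Label connected components of a 2D logical mask (4- or 8-connectivity).
// [[Rcpp::export(name = ".cc_label_2d")]]
IntegerVector cc_label_2d(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 2) stop("dim must have length 2");
  const int n1 = dim[0], n2 = dim[1];
  const R_xlen_t n = (R_xlen_t)n1 * n2;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");

  std::vector<int> d1, d2;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b) {
      if (a == 0 && b == 0) continue;
      if (connectivity == 4 && std::abs(a) + std::abs(b) != 1) continue;
      d1.push_back(a); d2.push_back(b);
    }
  const int nd = (int)d1.size();

  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      int f = i + n1 * j;
      if (!mask[f] || lab[f]) continue;
      ++next;
      lab[f] = next;
      stack.clear();
      stack.push_back(f);
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int ci = cur % n1, cj = cur / n1;
        for (int q = 0; q < nd; ++q) {
          int ni = ci + d1[q], nj = cj + d2[q];
          if (ni < 0 || ni >= n1 || nj < 0 || nj >= n2) continue;
          int nf = ni + n1 * nj;
          if (mask[nf] && !lab[nf]) { lab[nf] = next; stack.push_back(nf); }
        }
      }
    }
  return lab;
}

// Multi-source Dijkstra inside a 3D mask with anisotropic (physical) step
// lengths. 26-neighborhood; edge weight = Euclidean physical distance
// between voxel centers, spacing = (s1, s2, s3) um/voxel per axis.
// seed_idx: 1-based flat indices of seed voxels; seed_label: integer label
// propagated from each seed (several seeds may share one label).
// Returns dist (um, Inf where unreached), pred (1-based flat index of the
// predecessor, 0 at seeds/unreached), label (0 where unreached).
// [[Rcpp::export(name = ".geodesic_paths")]]
List geodesic_paths(LogicalVector mask, IntegerVector dim, NumericVector spacing,
                    IntegerVector seed_idx, IntegerVector seed_label) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (spacing.size() != 3) stop("spacing must have length 3");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dim");
  if (seed_idx.size() != seed_label.size()) stop("seed_idx and seed_label lengths differ");

  std::vector<int> d1, d2, d3;
  std::vector<double> w;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        d1.push_back(a); d2.push_back(b); d3.push_back(c);
        double dx = a * spacing[0], dy = b * spacing[1], dz = c * spacing[2];
        w.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
      }
  const int nd = (int)d1.size();

  NumericVector dist(n, R_PosInf);
  IntegerVector pred(n, 0);
  IntegerVector lab(n, 0);

  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int s = 0; s < seed_idx.size(); ++s) {
    int f = seed_idx[s] - 1;
    if (f < 0 || f >= n) stop("seed index out of range");
    if (!mask[f]) stop("seed voxel is outside the mask");
    if (dist[f] > 0) {
      dist[f] = 0.0;
      lab[f] = seed_label[s];
      pq.push(QE(0.0, f));
    }
  }

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double dcur = top.first;
    int cur = top.second;
    if (dcur > dist[cur]) continue;
    int ci = cur % n1, rem = cur / n1;
    int cj = rem % n2, ck = rem / n2;
    for (int q = 0; q < nd; ++q) {
      int ni = ci + d1[q], nj = cj + d2[q], nk = ck + d3[q];
      if (ni < 0 || ni >= n1 || nj < 0 || nj >= n2 || nk < 0 || nk >= n3) continue;
      int nf = flat3(ni, nj, nk, n1, n2);
      if (!mask[nf]) continue;
      double nd_ = dcur + w[q];
      if (nd_ < dist[nf]) {
        dist[nf] = nd_;
        pred[nf] = cur + 1;
        lab[nf] = lab[cur];
        pq.push(QE(nd_, nf));
      }
    }
  }

  return List::create(_["dist"] = dist, _["pred"] = pred, _["label"] = lab);
}
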