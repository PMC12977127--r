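#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Mesh graph operations over a CSR adjacency: offsets (length N+1, 0-based
// positions into nbr), nbr (0-based vertex indices, sorted per vertex).

// BFS-ball mode filter on vertex labels. Each vertex receives the modal label
// within its <= radius-edge BFS ball (center included). Tie rule: keep the
// current label if it ties, else take the smallest tied label. When `region`
// is non-empty the BFS never crosses region boundaries.
// [[Rcpp::export]]
IntegerVector cpp_mode_filter_surface(IntegerVector labels,
                                      IntegerVector offsets, IntegerVector nbr,
                                      int radius, int iterations,
                                      IntegerVector region) {
  const int n = labels.size();
  const bool has_region = region.size() == n;
  IntegerVector cur = clone(labels);
  IntegerVector nxt(n);
  std::vector<int> stamp(n, -1), dist(n), ball;
  std::vector<int> labs, cnts;
  for (int it = 0; it < iterations; ++it) {
    Rcpp::checkUserInterrupt();
    for (int v = 0; v < n; ++v) {
      ball.clear();
      ball.push_back(v);
      stamp[v] = v + it * n;  // unique stamp per (vertex, iteration)
      const int st = stamp[v];
      dist[v] = 0;
      for (size_t h = 0; h < ball.size(); ++h) {
        const int u = ball[h];
        if (dist[u] == radius) continue;
        for (int k = offsets[u]; k < offsets[u + 1]; ++k) {
          const int w = nbr[k];
          if (stamp[w] == st) continue;
          if (has_region && region[w] != region[v]) continue;
          stamp[w] = st;
          dist[w] = dist[u] + 1;
          ball.push_back(w);
        }
      }
      labs.clear(); cnts.clear();
      const int self = cur[v];
      for (size_t h = 0; h < ball.size(); ++h) {
        const int lab = cur[ball[h]];
        size_t j = 0;
        for (; j < labs.size(); ++j)
          if (labs[j] == lab) { ++cnts[j]; break; }
        if (j == labs.size()) { labs.push_back(lab); cnts.push_back(1); }
      }
      int bestc = -1, best = self;
      for (size_t j = 0; j < labs.size(); ++j) {
        if (cnts[j] > bestc ||
            ((int)cnts[j] == bestc &&
             (labs[j] == self || (best != self && labs[j] < best)))) {
          bestc = cnts[j]; best = labs[j];
        }
      }
      nxt[v] = best;
    }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
    std::fill(stamp.begin(), stamp.end(), -1);
  }
  return cur;
}

// Multi-source BFS patch growth confined to regions. Seeds must be given in
// ascending patch-id order; the FIFO frontier guarantees breadth-first
// assignment with earlier seeds winning distance ties. Unreached vertices
// stay 0.
// [[Rcpp::export]]
IntegerVector cpp_grow_patches(IntegerVector offsets, IntegerVector nbr,
                               IntegerVector region, IntegerVector seed_vertex,
                               IntegerVector seed_patch) {
  const int n = region.size();
  IntegerVector patch(n, 0);
  std::queue<int> q;
  for (int i = 0; i < seed_vertex.size(); ++i) {
    const int v = seed_vertex[i];
    if (patch[v] == 0) { patch[v] = seed_patch[i]; q.push(v); }
  }
  while (!q.empty()) {
    const int u = q.front();
    q.pop();
    for (int k = offsets[u]; k < offsets[u + 1]; ++k) {
      const int w = nbr[k];
      if (patch[w] != 0 || region[w] != region[u]) continue;
      patch[w] = patch[u];
      q.push(w);
    }
  }
  return patch;
}

// Connected components among vertices sharing the same value of `ids`
// (patch or region). Components numbered 1..K in vertex scan order.
// [[Rcpp::export]]
IntegerVector cpp_mesh_components(IntegerVector offsets, IntegerVector nbr,
                                  IntegerVector ids) {
  const int n = ids.size();
  IntegerVector comp(n, 0);
  int c = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (comp[s]) continue;
    ++c;
    comp[s] = c;
    stack.push_back(s);
    while (!stack.empty()) {
      const int u = stack.back();
      stack.pop_back();
      for (int k = offsets[u]; k < offsets[u + 1]; ++k) {
        const int w = nbr[k];
        if (!comp[w] && ids[w] == ids[s]) { comp[w] = c; stack.push_back(w); }
      }
    }
  }
  return comp;
}

// Classic (max-min) symmetric Hausdorff distance between two point sets.
// [[Rcpp::export]]
double cpp_hausdorff(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  double h = 0.0;
  for (int i = 0; i < na; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
                   dz = A(i, 2) - B(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < dmin) dmin = d;
    }
    if (dmin > h) h = dmin;
  }
  for (int j = 0; j < nb; ++j) {
    double dmin = R_PosInf;
    for (int i = 0; i < na; ++i) {
      const double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
                   dz = A(i, 2) - B(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < dmin) dmin = d;
    }
    if (dmin > h) h = dmin;
  }
  return std::sqrt(h);
}
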