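#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving.
static inline int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static inline void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// Connected components of suprathreshold voxels, positive and negative
// separately. adj_ptr/adj_idx are a 0-based CSR adjacency. Returns 1-based
// cluster labels in first-seen (ascending voxel id of the component root
// scan) order, 0 for subthreshold voxels.
// [[Rcpp::export]]
IntegerVector cluster_labels_cpp(NumericVector t, double thr,
                                 IntegerVector adj_ptr, IntegerVector adj_idx) {
  const int V = t.size();
  std::vector<int> sign(V, 0);
  for (int v = 0; v < V; ++v) {
    if (t[v] > thr) sign[v] = 1;
    else if (t[v] < -thr) sign[v] = -1;
  }
  std::vector<int> parent(V);
  for (int v = 0; v < V; ++v) parent[v] = v;
  for (int v = 0; v < V; ++v) {
    if (!sign[v]) continue;
    for (int k = adj_ptr[v]; k < adj_ptr[v + 1]; ++k) {
      int j = adj_idx[k];
      if (sign[j] == sign[v]) uf_union(parent, v, j);
    }
  }
  IntegerVector labels(V, 0);
  std::vector<int> lab(V, 0);
  int next = 0;
  for (int v = 0; v < V; ++v) {
    if (!sign[v]) continue;
    int r = uf_find(parent, v);
    if (lab[r] == 0) lab[r] = ++next;
    labels[v] = lab[r];
  }
  return labels;
}

// Permutation null of the max cluster |t_sum|. D is the n x V matrix of
// paired BI - NBI differences; signs is a P x n matrix of +/-1 subject
// sign flips. For each permutation the dependent-samples t map is computed
// (sign flips leave per-voxel sums of squares unchanged, so only the mean
// needs recomputing), suprathreshold voxels are clustered per sign, and the
// largest absolute cluster t-sum is recorded (0 when no voxel passes).
// [[Rcpp::export]]
NumericVector perm_max_tsum_cpp(NumericMatrix D, NumericMatrix signs, double thr,
                                IntegerVector adj_ptr, IntegerVector adj_idx) {
  const int n = D.nrow(), V = D.ncol(), P = signs.nrow();
  if (signs.ncol() != n) stop("signs must have one column per subject");
  std::vector<double> SS(V, 0.0);
  for (int v = 0; v < V; ++v) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += D(i, v) * D(i, v);
    SS[v] = s;
  }
  NumericVector out(P);
  std::vector<double> tval(V);
  std::vector<int> sign(V), parent(V);
  std::vector<double> csum(V);
  const double inv_n = 1.0 / n;

  for (int p = 0; p < P; ++p) {
    for (int v = 0; v < V; ++v) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += signs(p, i) * D(i, v);
      m *= inv_n;
      double var = (SS[v] - n * m * m) / (n - 1);
      double t = (var > 0.0) ? m / std::sqrt(var * inv_n) : 0.0;
      tval[v] = t;
      sign[v] = (t > thr) ? 1 : (t < -thr ? -1 : 0);
      parent[v] = v;
      csum[v] = 0.0;
    }
    for (int v = 0; v < V; ++v) {
      if (!sign[v]) continue;
      for (int k = adj_ptr[v]; k < adj_ptr[v + 1]; ++k) {
        int j = adj_idx[k];
        if (sign[j] == sign[v]) uf_union(parent, v, j);
      }
    }
    for (int v = 0; v < V; ++v) {
      if (sign[v]) csum[uf_find(parent, v)] += tval[v];
    }
    double best = 0.0;
    for (int v = 0; v < V; ++v) {
      double a = std::fabs(csum[v]);
      if (a > best) best = a;
    }
    out[p] = best;
  }
  return out;
}
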