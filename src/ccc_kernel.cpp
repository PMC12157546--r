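#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scalar ARI from two 0-based label vectors. The expression sequence
// (pair counts m*(m-1)/2, expected = ca*cb/cn, max = 0.5*(ca+cb)) mirrors
// the R reference implementation exactly: all pair-count sums are
// integer-valued doubles below 2^53, so both paths produce bit-identical
// IEEE results.
static double ari_pair(const int* l1, const int* l2, int n, int k1, int k2,
                       std::vector<double>& cells,
                       std::vector<double>& a, std::vector<double>& b) {
  cells.assign(static_cast<size_t>(k1) * k2, 0.0);
  a.assign(k1, 0.0);
  b.assign(k2, 0.0);
  for (int t = 0; t < n; ++t) {
    cells[static_cast<size_t>(l1[t]) * k2 + l2[t]] += 1.0;
    a[l1[t]] += 1.0;
    b[l2[t]] += 1.0;
  }
  double sij = 0.0, ca = 0.0, cb = 0.0;
  for (size_t c = 0; c < cells.size(); ++c) sij += cells[c] * (cells[c] - 1) / 2;
  for (int i = 0; i < k1; ++i) ca += a[i] * (a[i] - 1) / 2;
  for (int j = 0; j < k2; ++j) cb += b[j] * (b[j] - 1) / 2;
  double nn = static_cast<double>(n);
  double cn = nn * (nn - 1) / 2;
  double expected = ca * cb / cn;
  double max_index = 0.5 * (ca + cb);
  double den = max_index - expected;
  if (den == 0.0) return 0.0;
  return (sij - expected) / den;
}

// [[Rcpp::export]]
NumericMatrix ari_batch_cpp(IntegerMatrix mx, IntegerMatrix my,
                            IntegerVector kx, IntegerVector ky,
                            LogicalVector vx, LogicalVector vy) {
  const int n = mx.nrow();
  const int nu = mx.ncol(), nv = my.ncol();
  NumericMatrix out(nu, nv);
  std::vector<double> cells, a, b;
  for (int u = 0; u < nu; ++u) {
    for (int v = 0; v < nv; ++v) {
      if (vx[u] && vy[v]) {
        out(u, v) = ari_pair(&mx(0, u), &my(0, v), n, kx[u], ky[v], cells, a, b);
      } else {
        out(u, v) = NA_REAL;
      }
    }
  }
  return out;
}

// Max-ARI (the CCC before clipping) over all valid partition combinations
// of one feature pair. Partition columns are ordered by ascending k, so the
// strict '>' update breaks argmax ties toward the smallest k_x, then the
// smallest k_y.
static void ccc_cell(const int* labels, int n,
                     const int* part_k, const int* part_valid,
                     int off_x, int np_x, int off_y, int np_y,
                     std::vector<double>& cells,
                     std::vector<double>& a, std::vector<double>& b,
                     double* value, int* best_kx, int* best_ky) {
  double best = NA_REAL;
  int bkx = NA_INTEGER, bky = NA_INTEGER;
  bool any = false;
  for (int u = 0; u < np_x; ++u) {
    if (!part_valid[off_x + u]) continue;
    const int* lx = labels + static_cast<size_t>(off_x + u) * n;
    for (int v = 0; v < np_y; ++v) {
      if (!part_valid[off_y + v]) continue;
      const int* ly = labels + static_cast<size_t>(off_y + v) * n;
      double r = ari_pair(lx, ly, n, part_k[off_x + u], part_k[off_y + v],
                          cells, a, b);
      if (!any || r > best) {
        best = r;
        bkx = part_k[off_x + u];
        bky = part_k[off_y + v];
        any = true;
      }
    }
  }
  if (any) {
    *value = best > 0.0 ? best : 0.0;
    *best_kx = bkx;
    *best_ky = bky;
  } else {
    *value = NA_REAL;
    *best_kx = NA_INTEGER;
    *best_ky = NA_INTEGER;
  }
}

// All-vs-all CCC over a condensed pair list. Cells are evaluated in
// contiguous chunks of condensed indices; each cell writes only its own
// slot (pure assignment, no accumulation), so the result is independent of
// chunk_size by construction.
// [[Rcpp::export]]
List ccc_condensed_cpp(IntegerMatrix labels, IntegerVector part_k,
                       IntegerVector part_valid,
                       IntegerVector feat_off, IntegerVector feat_np,
                       IntegerVector pair_i, IntegerVector pair_j,
                       int chunk_size) {
  const int n = labels.nrow();
  const R_xlen_t n_pairs = pair_i.size();
  NumericVector value(n_pairs);
  IntegerVector best_kx(n_pairs), best_ky(n_pairs);
  std::vector<double> cells, a, b;
  if (chunk_size < 1) chunk_size = 1;
  for (R_xlen_t c0 = 0; c0 < n_pairs; c0 += chunk_size) {
    R_xlen_t c1 = std::min(c0 + chunk_size, n_pairs);
    for (R_xlen_t idx = c0; idx < c1; ++idx) {
      int fi = pair_i[idx], fj = pair_j[idx];
      ccc_cell(labels.begin(), n, part_k.begin(), part_valid.begin(),
               feat_off[fi], feat_np[fi], feat_off[fj], feat_np[fj],
               cells, a, b, &value[idx], &best_kx[idx], &best_ky[idx]);
    }
  }
  return List::create(_["ccc"] = value, _["best_k_x"] = best_kx,
                      _["best_k_y"] = best_ky);
}

// Permutation null for one feature pair: CCC recomputed after reordering
// the second feature's samples by each column of `perms` (0-based).
// Reordering the samples of a feature permutes its partition labels the
// same way (quantile and categorical partitions are permutation
// equivariant), so the null reuses the precomputed partitions.
// [[Rcpp::export]]
NumericVector ccc_perm_null_cpp(IntegerMatrix mx, IntegerVector kx, LogicalVector vx,
                                IntegerMatrix my, IntegerVector ky, LogicalVector vy,
                                IntegerMatrix perms) {
  const int n = mx.nrow();
  const int nu = mx.ncol(), nv = my.ncol();
  const int P = perms.ncol();
  NumericVector out(P);
  std::vector<double> cells, a, b;
  std::vector<int> ly(static_cast<size_t>(n) * nv);
  for (int p = 0; p < P; ++p) {
    const int* perm = &perms(0, p);
    for (int v = 0; v < nv; ++v) {
      int* dst = ly.data() + static_cast<size_t>(v) * n;
      const int* src = &my(0, v);
      for (int t = 0; t < n; ++t) dst[t] = src[perm[t]];
    }
    double best = NA_REAL;
    bool any = false;
    for (int u = 0; u < nu; ++u) {
      if (!vx[u]) continue;
      for (int v = 0; v < nv; ++v) {
        if (!vy[v]) continue;
        double r = ari_pair(&mx(0, u), ly.data() + static_cast<size_t>(v) * n,
                            n, kx[u], ky[v], cells, a, b);
        if (!any || r > best) { best = r; any = true; }
      }
    }
    out[p] = any ? (best > 0.0 ? best : 0.0) : NA_REAL;
  }
  return out;
}
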