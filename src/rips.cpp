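// Vietoris-Rips persistent homology over Z/p, dimensions 0..2.
//
// The implementation follows the persistent-cohomology approach that makes
// Rips computations tractable: H0 by a union-find pass over sorted edges,
// higher degrees by reducing the coboundary matrix with the clearing
// optimisation and the apparent-pair shortcut, so that the vast majority of
// columns are retired after a single cofacet scan and never stored.
// Simplices are indexed in the combinatorial number system (colexicographic
// order); the simplexwise filtration order is (diameter, index) ascending.
//
// The default threshold is the enclosing radius of the metric space: at that
// scale the complex is a cone, hence contractible, so all homology in
// degrees >= 1 dies within the filtration and diagrams are complete.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <functional>
#include <queue>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef uint64_t index_t;

struct BinomTable {
  int N = 0, K = 0;
  std::vector<index_t> tab;
  void init(int n, int k) {
    N = n;
    K = k;
    tab.assign(static_cast<size_t>(n + 1) * (k + 1), 0);
    for (int i = 0; i <= n; ++i) {
      tab[static_cast<size_t>(i) * (K + 1)] = 1;
      for (int j = 1; j <= std::min(i, k); ++j)
        tab[static_cast<size_t>(i) * (K + 1) + j] = at(i - 1, j - 1) + at(i - 1, j);
    }
  }
  inline index_t at(int n, int k) const {
    if (k < 0 || n < 0 || k > n) return 0;
    return tab[static_cast<size_t>(n) * (K + 1) + k];
  }
};

struct HeapEntry {
  double diam;
  index_t idx;
  int coeff;
};

struct HeapCmp {
  // priority_queue keeps the "largest"; we want the minimal (diam, idx) on
  // top, so "less" means later in the filtration.
  bool operator()(const HeapEntry& a, const HeapEntry& b) const {
    return a.diam > b.diam || (a.diam == b.diam && a.idx > b.idx);
  }
};

typedef std::priority_queue<HeapEntry, std::vector<HeapEntry>, HeapCmp> ColumnHeap;

// Reduced columns are stored in "V-column" form: the list of d-simplices
// (with coefficients) whose summed coboundaries equal the reduced column.
// This keeps storage proportional to the number of column additions rather
// than to column length; entries are re-enumerated on demand.
struct VEntry {
  double diam;      // diameter of the d-simplex
  index_t packed;   // its packed vertices
  int coeff;
};

struct StoredColumn {
  int pivot_coeff;
  std::vector<VEntry> vcol;
};

struct Column {
  double diam;
  index_t packed;  // vertices packed 10 bits each, highest vertex in high bits
};

static inline int mod_inverse(int c, int p) {
  c %= p;
  if (c < 0) c += p;
  for (int x = 1; x < p; ++x)
    if ((c * x) % p == 1) return x;
  return 0;  // unreachable for prime p, c != 0
}

class RipsComplex {
 public:
  int n, prime, max_dim;
  double threshold;
  std::vector<double> D;  // n x n, row-major
  BinomTable binom;

  // outputs
  std::vector<std::vector<double>> births, deaths;  // per dim
  int essential_h0 = 0;

  RipsComplex(const NumericMatrix& dist, int maxdim, int p, double thr)
      : n(dist.nrow()), prime(p), max_dim(maxdim), threshold(thr) {
    // canonicalize: upper triangle wins, so d(i,j) == d(j,i) to the last bit
    // (graph shortest-path matrices can be asymmetric by rounding)
    D.resize(static_cast<size_t>(n) * n);
    for (int i = 0; i < n; ++i) {
      D[static_cast<size_t>(i) * n + i] = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double v = dist(i, j);
        D[static_cast<size_t>(i) * n + j] = v;
        D[static_cast<size_t>(j) * n + i] = v;
      }
    }
    binom.init(n + 1, maxdim + 3);
    births.resize(maxdim + 1);
    deaths.resize(maxdim + 1);
  }

  inline double d(int i, int j) const { return D[static_cast<size_t>(i) * n + j]; }

  double enclosing_radius() const {
    double best = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double mx = 0;
      for (int j = 0; j < n; ++j) mx = std::max(mx, d(i, j));
      best = std::min(best, mx);
    }
    return best;
  }

  inline index_t simplex_index(const int* v, int dim) const {
    index_t idx = 0;
    for (int i = 0; i <= dim; ++i) idx += binom.at(v[i], i + 1);
    return idx;
  }

  // decode colex index into vertices v[0] < ... < v[dim]
  void decode(index_t idx, int dim, int* v) const {
    int hi = n - 1;
    for (int k = dim + 1; k >= 1; --k) {
      // binary search: largest vert in [k-1, hi] with C(vert, k) <= idx
      int lo = k - 1, up = hi;
      while (lo < up) {
        int mid = (lo + up + 1) / 2;
        if (binom.at(mid, k) <= idx)
          lo = mid;
        else
          up = mid - 1;
      }
      v[k - 1] = lo;
      idx -= binom.at(lo, k);
      hi = lo - 1;
    }
  }

  inline double simplex_diam(const int* v, int dim) const {
    double mx = 0;
    for (int i = 0; i <= dim; ++i)
      for (int j = i + 1; j <= dim; ++j) mx = std::max(mx, d(v[i], v[j]));
    return mx;
  }

  // ---- dimension 0: union-find over sorted edges --------------------------

  std::vector<Column> edges;          // sorted ascending (diam, packed)
  std::vector<char> edge_is_tree;     // parallel to edges

  void build_edges() {
    edges.clear();
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i) {
        double dij = d(i, j);
        if (dij <= threshold)
          edges.push_back({dij, (static_cast<index_t>(j) << 10) | static_cast<index_t>(i)});
      }
    std::sort(edges.begin(), edges.end(), [](const Column& a, const Column& b) {
      return a.diam < b.diam || (a.diam == b.diam && a.packed < b.packed);
    });
    edge_is_tree.assign(edges.size(), 0);
  }

  void compute_dim0() {
    std::vector<int> parent(n), rank_(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) {
        parent[x] = parent[parent[x]];
        x = parent[x];
      }
      return x;
    };
    int ncomp = n;
    for (size_t e = 0; e < edges.size(); ++e) {
      int a = static_cast<int>(edges[e].packed & 1023);
      int b = static_cast<int>(edges[e].packed >> 10);
      int ra = find(a), rb = find(b);
      if (ra != rb) {
        if (rank_[ra] < rank_[rb]) std::swap(ra, rb);
        parent[rb] = ra;
        if (rank_[ra] == rank_[rb]) ++rank_[ra];
        edge_is_tree[e] = 1;
        --ncomp;
        if (edges[e].diam > 0) {
          births[0].push_back(0.0);
          deaths[0].push_back(edges[e].diam);
        }
      }
    }
    essential_h0 = ncomp;
  }

  // ---- coboundary machinery ----------------------------------------------

  // Enumerate cofacets of a simplex (vertices vs[0..dim]) in increasing
  // cofacet index order (= increasing added vertex).  Calls fn(v, pos, diam,
  // idx); fn returns false to stop the scan early.
  template <typename F>
  void scan_cofacets(const int* vs, int dim, double diam_s, F fn) const {
    index_t lo[5], hi[5];
    lo[0] = 0;
    for (int i = 0; i < dim + 1; ++i) lo[i + 1] = lo[i] + binom.at(vs[i], i + 1);
    hi[dim + 1] = 0;
    for (int i = dim; i >= 0; --i) hi[i] = hi[i + 1] + binom.at(vs[i], i + 2);
    int pos = 0;
    for (int v = 0; v < n; ++v) {
      if (pos <= dim && v == vs[pos]) {
        ++pos;
        continue;
      }
      double dm = diam_s;
      const double* row = &D[static_cast<size_t>(v) * n];
      for (int i = 0; i <= dim; ++i) dm = std::max(dm, row[vs[i]]);
      index_t idx = lo[pos] + binom.at(v, pos + 1) + hi[pos];
      if (!fn(v, pos, dm, idx)) return;
    }
  }

  // Maximal facet (in filtration order) of simplex with vertices ws[0..dim].
  void max_facet(const int* ws, int dim, int* out_verts, double& out_diam,
                 index_t& out_idx) const {
    double best_diam = -1;
    index_t best_idx = 0;
    int best_drop = -1;
    int fv[4];
    for (int dropi = 0; dropi <= dim; ++dropi) {
      int m = 0;
      for (int i = 0; i <= dim; ++i)
        if (i != dropi) fv[m++] = ws[i];
      double dm = simplex_diam(fv, dim - 1);
      index_t idx = simplex_index(fv, dim - 1);
      if (dm > best_diam || (dm == best_diam && idx > best_idx)) {
        best_diam = dm;
        best_idx = idx;
        best_drop = dropi;
      }
    }
    int m = 0;
    for (int i = 0; i <= dim; ++i)
      if (i != best_drop) out_verts[m++] = ws[i];
    out_diam = best_diam;
    out_idx = best_idx;
  }

  // If the pivot tau (dim d+1) is the minimal cofacet of its maximal facet
  // sigma*, (sigma*, tau) is an apparent pair; return true and describe
  // sigma*.  sign_out is the coefficient of tau in the coboundary of sigma*.
  bool apparent_owner(index_t tau_idx, double tau_diam, int d, int* owner_verts,
                      double& owner_diam, index_t& owner_idx, int& sign_out) const {
    int tv[4];
    decode(tau_idx, d + 1, tv);
    max_facet(tv, d + 1, owner_verts, owner_diam, owner_idx);
    // tau must be the minimal cofacet of the owner in (diam, idx) order.
    // The scan runs in index order, so after locating tau we must keep
    // scanning: a later-index cofacet may still have a smaller diameter.
    bool ok = true;
    int sign_pos = -1;
    scan_cofacets(owner_verts, d, owner_diam,
                  [&](int v, int pos, double dm, index_t idx) -> bool {
                    if (dm > threshold) return true;
                    if (dm < tau_diam || (dm == tau_diam && idx < tau_idx)) {
                      ok = false;
                      return false;  // a smaller cofacet exists
                    }
                    if (idx == tau_idx) {
                      sign_pos = pos;
                      // if tau realises the smallest possible diameter no
                      // later cofacet can precede it
                      return tau_diam != owner_diam;
                    }
                    return true;
                  });
    if (!ok || sign_pos < 0) return false;
    sign_out = (sign_pos % 2 == 0) ? 1 : prime - 1;
    return true;
  }

  // push multiplier * coboundary(simplex described by a VEntry) into heap
  void push_coboundary(const VEntry& e, int d, int multiplier, ColumnHeap& heap) const {
    int vs[4];
    for (int i = 0; i <= d; ++i)
      vs[i] = static_cast<int>((e.packed >> (10 * i)) & 1023);
    scan_cofacets(vs, d, e.diam, [&](int v, int pos, double dm, index_t idx) -> bool {
      if (dm <= threshold) {
        int s = (pos % 2 == 0) ? 1 : prime - 1;
        heap.push({dm, idx, (s * multiplier) % prime});
      }
      return true;
    });
  }

  bool pop_pivot(ColumnHeap& heap, HeapEntry& out) const {
    while (!heap.empty()) {
      HeapEntry e = heap.top();
      heap.pop();
      long long c = e.coeff;
      while (!heap.empty() && heap.top().idx == e.idx) {
        c += heap.top().coeff;
        heap.pop();
      }
      int cc = static_cast<int>(((c % prime) + prime) % prime);
      if (cc != 0) {
        out = e;
        out.coeff = cc;
        return true;
      }
    }
    return false;
  }

  // ---- matrix reduction for one dimension ---------------------------------

  // columns: d-simplices (diam, packed vertices), must be processed in
  // reverse filtration order.  cleared_next collects paired (d+1)-simplices.
  void reduce_dimension(int d, std::vector<Column>& columns,
                        std::unordered_set<index_t>* cleared_next) {
    std::sort(columns.begin(), columns.end(), [](const Column& a, const Column& b) {
      return a.diam > b.diam || (a.diam == b.diam && a.packed > b.packed);
    });
    std::unordered_map<index_t, uint32_t> pivot_hash;
    std::vector<StoredColumn> stored;
    int vs[4], owner_verts[4], ov2[4];

    for (size_t ci = 0; ci < columns.size(); ++ci) {
      if ((ci & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
      const Column& col = columns[ci];
      for (int i = 0; i <= d; ++i)
        vs[i] = static_cast<int>((col.packed >> (10 * i)) & 1023);
      std::sort(vs, vs + d + 1);
      double sigma_diam = col.diam;
      index_t sigma_idx = simplex_index(vs, d);

      // ---- initial cofacet scan with the emergent/apparent shortcut ----
      std::vector<HeapEntry> init;
      bool done = false;
      bool shortcut_allowed = true;
      scan_cofacets(vs, d, sigma_diam,
                    [&](int v, int pos, double dm, index_t idx) -> bool {
                      if (dm > threshold) return true;
                      int sign = (pos % 2 == 0) ? 1 : prime - 1;
                      if (shortcut_allowed && dm == sigma_diam) {
                        // minimal cofacet; apparent iff sigma is tau's max facet
                        int tv[4];
                        int m = 0;
                        for (int i = 0; i <= d; ++i) {
                          if (m == pos) tv[m++] = v;
                          tv[m++] = vs[i];
                        }
                        if (m == d + 1) tv[m++] = v;
                        double mf_diam;
                        index_t mf_idx;
                        max_facet(tv, d + 1, ov2, mf_diam, mf_idx);
                        if (mf_idx == sigma_idx && mf_diam == sigma_diam) {
                          // zero-persistence apparent pair: retire column
                          if (cleared_next) cleared_next->insert(idx);
                          done = true;
                          return false;
                        }
                        shortcut_allowed = false;  // min cofacet seen, keep going
                      }
                      init.push_back({dm, idx, sign});
                      return true;
                    });
      if (done) continue;

      ColumnHeap heap(HeapCmp(), std::move(init));
      std::vector<VEntry> vcur;
      vcur.push_back({sigma_diam, col.packed, 1});
      bool paired = false;
      HeapEntry piv;
      double prev_pivot_diam = -1;
      index_t prev_pivot_idx = 0;
      while (pop_pivot(heap, piv)) {
        if (prev_pivot_diam >= 0 &&
            !(piv.diam > prev_pivot_diam ||
              (piv.diam == prev_pivot_diam && piv.idx > prev_pivot_idx)))
          stop("internal error: pivot did not advance during reduction");
        prev_pivot_diam = piv.diam;
        prev_pivot_idx = piv.idx;
        auto it = pivot_hash.find(piv.idx);
        if (it != pivot_hash.end()) {
          const StoredColumn& S = stored[it->second];
          int lambda =
              (prime - (piv.coeff * mod_inverse(S.pivot_coeff, prime)) % prime) % prime;
          heap.push(piv);
          for (const VEntry& e : S.vcol) {
            int c = (e.coeff * lambda) % prime;
            if (c == 0) continue;
            push_coboundary(e, d, c, heap);
            vcur.push_back({e.diam, e.packed, c});
          }
          continue;
        }
        double owner_diam;
        index_t owner_idx;
        int sign;
        if (apparent_owner(piv.idx, piv.diam, d, owner_verts, owner_diam, owner_idx,
                           sign)) {
          if (owner_idx == sigma_idx) {
            // sigma's own apparent pair (positive persistence allowed)
            if (piv.diam > sigma_diam) {
              births[d].push_back(sigma_diam);
              deaths[d].push_back(piv.diam);
            }
            if (cleared_next) cleared_next->insert(piv.idx);
            paired = true;
            break;
          }
          int lambda =
              (prime - (piv.coeff * mod_inverse(sign, prime)) % prime) % prime;
          heap.push(piv);
          VEntry ov;
          ov.diam = owner_diam;
          ov.packed = 0;
          for (int i = 0; i <= d; ++i)
            ov.packed |= static_cast<index_t>(owner_verts[i]) << (10 * i);
          ov.coeff = lambda;
          push_coboundary(ov, d, lambda, heap);
          vcur.push_back(ov);
          continue;
        }
        // claim the pivot and remember the column in V form
        if (piv.diam > sigma_diam) {
          births[d].push_back(sigma_diam);
          deaths[d].push_back(piv.diam);
        }
        if (cleared_next) cleared_next->insert(piv.idx);
        StoredColumn S;
        S.pivot_coeff = piv.coeff;
        S.vcol = std::move(vcur);
        pivot_hash[piv.idx] = static_cast<uint32_t>(stored.size());
        stored.push_back(std::move(S));
        paired = true;
        break;
      }
      if (!paired && heap.empty()) {
        // essential class within the truncated filtration
        births[d].push_back(sigma_diam);
        deaths[d].push_back(R_PosInf);
      }
    }
  }

  void compute() {
    if (!R_finite(threshold)) threshold = enclosing_radius();
    build_edges();
    compute_dim0();
    if (max_dim < 1) return;

    std::vector<Column> cols1;
    cols1.reserve(edges.size());
    for (size_t e = 0; e < edges.size(); ++e)
      if (!edge_is_tree[e]) cols1.push_back(edges[e]);
    std::unordered_set<index_t> cleared2;
    reduce_dimension(1, cols1, max_dim >= 2 ? &cleared2 : nullptr);
    if (max_dim < 2) return;

    std::vector<Column> cols2;
    {
      // count first to reserve exactly (the list can be large)
      size_t cnt = 0;
      for (int k = 2; k < n; ++k)
        for (int j = 1; j < k; ++j) {
          double djk = d(j, k);
          if (djk > threshold) continue;
          const double* rj = &D[static_cast<size_t>(j) * n];
          const double* rk = &D[static_cast<size_t>(k) * n];
          for (int i = 0; i < j; ++i) {
            double dm = std::max(djk, std::max(rj[i], rk[i]));
            if (dm <= threshold) ++cnt;
          }
        }
      cols2.reserve(cnt);
      int tv[3];
      for (int k = 2; k < n; ++k)
        for (int j = 1; j < k; ++j) {
          double djk = d(j, k);
          if (djk > threshold) continue;
          const double* rj = &D[static_cast<size_t>(j) * n];
          const double* rk = &D[static_cast<size_t>(k) * n];
          for (int i = 0; i < j; ++i) {
            double dm = std::max(djk, std::max(rj[i], rk[i]));
            if (dm > threshold) continue;
            tv[0] = i;
            tv[1] = j;
            tv[2] = k;
            if (!cleared2.empty() &&
                cleared2.count(simplex_index(tv, 2)))
              continue;
            cols2.push_back({dm, (static_cast<index_t>(k) << 20) |
                                     (static_cast<index_t>(j) << 10) |
                                     static_cast<index_t>(i)});
          }
        }
    }
    reduce_dimension(2, cols2, nullptr);
  }
};

// [[Rcpp::export]]
List cpp_rips_persistence(NumericMatrix dist, int max_dim, int prime,
                          double threshold) {
  int n = dist.nrow();
  if (n != dist.ncol()) stop("distance matrix must be square");
  if (n > 1023) stop("point clouds above 1023 points are not supported");
  if (max_dim < 0 || max_dim > 2) stop("max_dim must be 0, 1 or 2");
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (!R_finite(dist(i, j))) stop("non-finite distances are not allowed");

  RipsComplex rc(dist, max_dim, prime, threshold);
  rc.compute();

  List out(max_dim + 1);
  for (int d = 0; d <= max_dim; ++d) {
    int m = rc.births[d].size();
    NumericMatrix pd(m, 2);
    for (int i = 0; i < m; ++i) {
      pd(i, 0) = rc.births[d][i];
      pd(i, 1) = rc.deaths[d][i];
    }
    colnames(pd) = CharacterVector::create("birth", "death");
    out[d] = pd;
  }
  return List::create(_["pairs"] = out, _["essential_h0"] = rc.essential_h0,
                      _["threshold"] = rc.threshold);
}

// [[Rcpp::export]]
double cpp_enclosing_radius(NumericMatrix dist) {
  int n = dist.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double mx = 0;
    for (int j = 0; j < n; ++j) mx = std::max(mx, dist(i, j));
    best = std::min(best, mx);
  }
  return best;
}
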