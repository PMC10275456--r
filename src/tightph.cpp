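// Core computational engine: Vietoris-Rips filtration enumeration, persistence
// by coboundary (with clearing) and by boundary reduction, on-the-fly
// birth-cycle extraction, greedy cycle shortening and local smoothing.
// Chains are over Z2; simplices are identified by their filtration index.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <set>
#include <vector>
#include <algorithm>
#include <functional>
#include <random>
#include <cstdint>

using namespace Rcpp;

typedef std::uint64_t u64;
typedef std::vector<int> Col;

// ---------- small utilities ----------

// Z2 addition of two strictly increasing index vectors.
static Col xor_sorted(const Col& a, const Col& b) {
  Col out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (a[i] > b[j]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  return out;
}

// Encode a sorted vertex tuple (up to 4 vertices, 0-based) as a 64-bit key.
static inline u64 skey(const int* v, int nv, u64 B) {
  u64 k = 0;
  for (int a = 0; a < 4; ++a) k = k * B + (a < nv ? (u64)(v[a] + 1) : 0);
  return k;
}

// Access into the m x 4 vertex matrix (-1 padded).
struct FView {
  const int* v;
  const int* dm;
  const double* di;
  int m, n;
  u64 B;
  inline int vert(int i, int k) const { return v[i + (size_t)k * m]; }
  inline int sdim(int i) const { return dm[i]; }
  inline double diam(int i) const { return di[i]; }
  inline u64 key(int i) const {
    int vv[4];
    int nv = sdim(i) + 1;
    for (int a = 0; a < nv; ++a) vv[a] = vert(i, a);
    return skey(vv, nv, B);
  }
};

static FView make_view(const IntegerMatrix& verts, const IntegerVector& sdim,
                       const NumericVector& sdiam, int n) {
  FView f;
  f.v = verts.begin();
  f.dm = sdim.begin();
  f.di = sdiam.begin();
  f.m = verts.nrow();
  f.n = n;
  f.B = (u64)n + 1;
  return f;
}

static std::unordered_map<u64, int> build_index(const FView& f) {
  std::unordered_map<u64, int> idx;
  idx.reserve((size_t)f.m * 2);
  for (int i = 0; i < f.m; ++i) idx.emplace(f.key(i), i);
  return idx;
}

// Sorted adjacency lists from the 1-skeleton.
static std::vector<Col> build_adj(const FView& f) {
  std::vector<Col> adj(f.n);
  for (int i = 0; i < f.m; ++i) {
    if (f.sdim(i) != 1) continue;
    int a = f.vert(i, 0), b = f.vert(i, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  for (int v = 0; v < f.n; ++v) std::sort(adj[v].begin(), adj[v].end());
  return adj;
}

// Facet filtration indices of simplex i (ascending).
static Col facets_of(const FView& f, const std::unordered_map<u64, int>& idx, int i) {
  Col out;
  int d = f.sdim(i);
  if (d == 0) return out;
  int vv[4];
  for (int a = 0; a <= d; ++a) vv[a] = f.vert(i, a);
  int fac[4];
  for (int drop = 0; drop <= d; ++drop) {
    int p = 0;
    for (int a = 0; a <= d; ++a) if (a != drop) fac[p++] = vv[a];
    std::unordered_map<u64, int>::const_iterator it = idx.find(skey(fac, d, f.B));
    if (it == idx.end()) stop("filtration is not closed under faces");
    out.push_back(it->second);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Cofacet filtration indices of simplex i (ascending); complex truncated at tau
// so only tuples present in the index qualify.
static Col cofacets_of(const FView& f, const std::unordered_map<u64, int>& idx,
                       const std::vector<Col>& adj, int i) {
  Col out;
  int d = f.sdim(i);
  if (d >= 3) return out;
  int vv[4];
  for (int a = 0; a <= d; ++a) vv[a] = f.vert(i, a);
  const Col& cand = adj[vv[0]];
  int ext[4];
  for (size_t c = 0; c < cand.size(); ++c) {
    int w = cand[c];
    bool dup = false;
    for (int a = 0; a <= d; ++a) if (vv[a] == w) { dup = true; break; }
    if (dup) continue;
    int p = 0, a = 0;
    while (a <= d && vv[a] < w) ext[p++] = vv[a++];
    ext[p++] = w;
    while (a <= d) ext[p++] = vv[a++];
    std::unordered_map<u64, int>::const_iterator it = idx.find(skey(ext, d + 2, f.B));
    if (it != idx.end()) out.push_back(it->second);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// ---------- filtration construction ----------

// Enumerate the Vietoris-Rips filtration (cliques of the tau-truncated
// distance graph, dims 0..max_dim) in filtration order: diameter ascending,
// dimension ascending, then vertex-lexicographic; perm_seed >= 0 replaces the
// lexicographic tie-break by a seeded random order within (diameter, dim) ties.
// [[Rcpp::export]]
List vr_filtration_cpp(int n, IntegerVector ei, IntegerVector ej,
                       NumericVector ed, double tau, int max_dim,
                       int perm_seed) {
  if (max_dim < 1 || max_dim > 3) stop("max_dim must be 1, 2 or 3");
  if ((u64)n + 1 >= ((u64)1 << 15)) stop("too many points for 64-bit simplex keys");
  size_t ne = ei.size();
  // adjacency with distances
  std::vector<std::vector<std::pair<int, double> > > nb(n);
  std::unordered_map<u64, double> dmap;
  dmap.reserve(ne * 2);
  u64 B = (u64)n + 1;
  for (size_t e = 0; e < ne; ++e) {
    int a = ei[e], b = ej[e];
    double d = ed[e];
    if (a < 0 || b < 0 || a >= n || b >= n || a >= b) stop("bad edge list");
    if (!(d <= tau)) continue;
    nb[a].push_back(std::make_pair(b, d));
    dmap[(u64)a * B + (u64)b] = d;
  }
  for (int v = 0; v < n; ++v) std::sort(nb[v].begin(), nb[v].end());

  std::vector<int> V0, V1, V2, V3;  // flattened vertex tuples per dim
  std::vector<double> D1, D2, D3;
  // edges
  for (int a = 0; a < n; ++a)
    for (size_t t = 0; t < nb[a].size(); ++t) {
      V1.push_back(a);
      V1.push_back(nb[a][t].first);
      D1.push_back(nb[a][t].second);
    }
  std::vector<std::pair<int, double> > tmp;
  if (max_dim >= 2) {
    for (int a = 0; a < n; ++a) {
      for (size_t t = 0; t < nb[a].size(); ++t) {
        int b = nb[a][t].first;
        double dab = nb[a][t].second;
        // common neighbours c > b of a and b
        size_t i = 0, j = 0;
        const std::vector<std::pair<int, double> >& A = nb[a];
        const std::vector<std::pair<int, double> >& Bv = nb[b];
        while (i < A.size() && j < Bv.size()) {
          if (A[i].first < Bv[j].first) ++i;
          else if (A[i].first > Bv[j].first) ++j;
          else {
            int c = A[i].first;
            if (c > b) {
              double diam = std::max(dab, std::max(A[i].second, Bv[j].second));
              V2.push_back(a); V2.push_back(b); V2.push_back(c);
              D2.push_back(diam);
              if (max_dim >= 3) {
                // common neighbours e > c of a, b, c
                size_t x = i + 1, y = j + 1;
                const std::vector<std::pair<int, double> >& Cv = nb[c];
                size_t z = 0;
                while (x < A.size() && y < Bv.size() && z < Cv.size()) {
                  int va = A[x].first, vb = Bv[y].first, vc = Cv[z].first;
                  int mx = std::max(va, std::max(vb, vc));
                  if (va < mx) { ++x; continue; }
                  if (vb < mx) { ++y; continue; }
                  if (vc < mx) { ++z; continue; }
                  double diam2 = std::max(diam,
                      std::max(A[x].second, std::max(Bv[y].second, Cv[z].second)));
                  V3.push_back(a); V3.push_back(b); V3.push_back(c); V3.push_back(mx);
                  D3.push_back(diam2);
                  ++x; ++y; ++z;
                }
              }
            }
            ++i; ++j;
          }
        }
      }
    }
  }
  (void)tmp;
  size_t m = (size_t)n + D1.size() + D2.size() + D3.size();
  IntegerMatrix verts((int)m, 4);
  IntegerVector sdim((int)m);
  NumericVector sdiam((int)m);
  std::vector<int> vs((size_t)m * 4, -1);
  std::vector<int> dms(m);
  std::vector<double> dis(m);
  size_t pos = 0;
  for (int v = 0; v < n; ++v) { vs[pos * 4] = v; dms[pos] = 0; dis[pos] = 0.0; ++pos; }
  for (size_t e = 0; e < D1.size(); ++e) {
    vs[pos * 4] = V1[2 * e]; vs[pos * 4 + 1] = V1[2 * e + 1];
    dms[pos] = 1; dis[pos] = D1[e]; ++pos;
  }
  for (size_t t = 0; t < D2.size(); ++t) {
    vs[pos * 4] = V2[3 * t]; vs[pos * 4 + 1] = V2[3 * t + 1]; vs[pos * 4 + 2] = V2[3 * t + 2];
    dms[pos] = 2; dis[pos] = D2[t]; ++pos;
  }
  for (size_t q = 0; q < D3.size(); ++q) {
    vs[pos * 4] = V3[4 * q]; vs[pos * 4 + 1] = V3[4 * q + 1];
    vs[pos * 4 + 2] = V3[4 * q + 2]; vs[pos * 4 + 3] = V3[4 * q + 3];
    dms[pos] = 3; dis[pos] = D3[q]; ++pos;
  }
  // filtration order
  std::vector<int> ord(m);
  for (size_t i = 0; i < m; ++i) ord[i] = (int)i;
  std::vector<double> tie;
  if (perm_seed >= 0) {
    std::mt19937 rng((std::uint32_t)perm_seed);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    tie.resize(m);
    for (size_t i = 0; i < m; ++i) tie[i] = U(rng);
  }
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (dis[a] != dis[b]) return dis[a] < dis[b];
    if (dms[a] != dms[b]) return dms[a] < dms[b];
    if (perm_seed >= 0 && tie[a] != tie[b]) return tie[a] < tie[b];
    for (int k = 0; k < 4; ++k)
      if (vs[(size_t)a * 4 + k] != vs[(size_t)b * 4 + k])
        return vs[(size_t)a * 4 + k] < vs[(size_t)b * 4 + k];
    return false;
  });
  for (size_t i = 0; i < m; ++i) {
    int s = ord[i];
    for (int k = 0; k < 4; ++k) verts((int)i, k) = vs[(size_t)s * 4 + k];
    sdim[(int)i] = dms[s];
    sdiam[(int)i] = dis[s];
  }
  return List::create(_["verts"] = verts, _["dim"] = sdim, _["diam"] = sdiam,
                      _["n_points"] = n, _["tau"] = tau, _["max_dim"] = max_dim);
}

// ---------- persistence: coboundary route with clearing ----------

// H0 pairs by union-find (elder rule with filtration-index ties), then for
// each d >= 1 reduce the coboundary columns of d-simplices in reverse
// filtration order; destroyer columns identified at dimension d-1 are cleared.
// Returns per-dimension (creator, destroyer) index pairs (-1 = essential).
// [[Rcpp::export]]
List ph_pairs_cpp(IntegerMatrix verts, IntegerVector sdim, NumericVector sdiam,
                  int n, int max_dim) {
  FView f = make_view(verts, sdim, sdiam, n);
  std::unordered_map<u64, int> idx = build_index(f);
  std::vector<Col> adj = build_adj(f);
  int m = f.m;

  // ---- H0 by union-find ----
  std::vector<int> vfi(n, -1);  // vertex id -> filtration index
  for (int i = 0; i < m; ++i)
    if (f.sdim(i) == 0) vfi[f.vert(i, 0)] = i;
  std::vector<int> parent(n), creator(n);
  for (int v = 0; v < n; ++v) parent[v] = v, creator[v] = vfi[v];
  std::function<int(int)> findr = [&](int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  };
  std::vector<int> cre0, des0;
  std::vector<char> is_destroyer(m, 0);
  for (int i = 0; i < m; ++i) {
    if (f.sdim(i) != 1) continue;
    int a = findr(f.vert(i, 0)), b = findr(f.vert(i, 1));
    if (a == b) continue;
    int ca = creator[a], cb = creator[b];
    int dies = std::max(ca, cb), lives = std::min(ca, cb);
    cre0.push_back(dies);
    des0.push_back(i);
    is_destroyer[i] = 1;
    parent[a] = b;
    creator[b] = lives;
  }
  // essential components
  std::vector<char> seen(n, 0);
  for (int v = 0; v < n; ++v) {
    int r = findr(v);
    if (!seen[r]) { seen[r] = 1; cre0.push_back(creator[r]); des0.push_back(-1); }
  }

  List out(max_dim);  // slot d holds dim-d pairs (d = 0 .. max_dim-1)
  out[0] = List::create(_["creator"] = wrap(cre0), _["destroyer"] = wrap(des0));

  // ---- coboundary reduction for d = 1 .. max_dim-1 ----
  for (int d = 1; d <= max_dim - 1; ++d) {
    std::vector<int> cre, des;
    std::vector<char> next_destroyer(m, 0);
    // columns in reverse filtration order; entries transformed t = m-1-idx so
    // that ascending vectors with pivot at the back realize the anti-transpose.
    std::unordered_map<int, int> pivot_owner;  // pivot (transformed) -> slot
    std::vector<Col> cols;
    for (int i = m - 1; i >= 0; --i) {
      if (f.sdim(i) != d) continue;
      if (is_destroyer[i]) continue;  // clearing
      Col c = cofacets_of(f, idx, adj, i);
      for (size_t k = 0; k < c.size(); ++k) c[k] = m - 1 - c[k];
      std::sort(c.begin(), c.end());
      while (!c.empty()) {
        int p = c.back();
        std::unordered_map<int, int>::iterator it = pivot_owner.find(p);
        if (it == pivot_owner.end()) break;
        c = xor_sorted(c, cols[it->second]);
      }
      if (c.empty()) {
        cre.push_back(i);
        des.push_back(-1);
      } else {
        int p = c.back();
        int dst = m - 1 - p;
        cre.push_back(i);
        des.push_back(dst);
        next_destroyer[dst] = 1;
        pivot_owner[p] = (int)cols.size();
        cols.push_back(c);
      }
    }
    is_destroyer = next_destroyer;
    out[d] = List::create(_["creator"] = wrap(cre), _["destroyer"] = wrap(des));
  }
  return out;
}

// ---------- persistence: full boundary reduction ----------

// Standard left-to-right reduction of the boundary matrix; optionally records
// the full matrix of reduction operations V so that the columns V(sigma) of
// creators (the birth-cycles) can be read off directly.
// [[Rcpp::export]]
List boundary_pairs_cpp(IntegerMatrix verts, IntegerVector sdim,
                        NumericVector sdiam, int n, bool want_v) {
  FView f = make_view(verts, sdim, sdiam, n);
  std::unordered_map<u64, int> idx = build_index(f);
  int m = f.m;
  std::unordered_map<int, int> pivot_owner;      // pivot row -> column index
  std::unordered_map<int, Col> R;                // reduced nonzero columns
  std::unordered_map<int, Col> V;                // reduction operations
  std::vector<int> cre, des, credim;
  std::vector<char> paired(m, 0);
  for (int j = 0; j < m; ++j) {
    int d = f.sdim(j);
    Col c = (d == 0) ? Col() : facets_of(f, idx, j);
    Col v;
    if (want_v) v.push_back(j);
    while (!c.empty()) {
      int p = c.back();
      std::unordered_map<int, int>::iterator it = pivot_owner.find(p);
      if (it == pivot_owner.end()) break;
      int k = it->second;
      c = xor_sorted(c, R[k]);
      if (want_v) v = xor_sorted(v, V[k]);
    }
    if (c.empty()) {
      // creator of a dim-d class; paired later if some column pivots on j
      cre.push_back(j);
      des.push_back(-1);
      credim.push_back(d);
      if (want_v) V[j] = v;
    } else {
      int p = c.back();
      pivot_owner[p] = j;
      R[j] = c;
      if (want_v) V[j] = v;
      paired[p] = 1;
      // record pair on the creator entry later
    }
  }
  // fill destroyers
  std::unordered_map<int, int> dmapp;  // creator -> destroyer
  for (std::unordered_map<int, int>::iterator it = pivot_owner.begin();
       it != pivot_owner.end(); ++it)
    dmapp[it->first] = it->second;
  for (size_t q = 0; q < cre.size(); ++q) {
    std::unordered_map<int, int>::iterator it = dmapp.find(cre[q]);
    if (it != dmapp.end()) des[q] = it->second;
  }
  List vout;
  if (want_v) {
    // return V columns of creators only
    std::vector<int> keys;
    List vc(cre.size());
    for (size_t q = 0; q < cre.size(); ++q) vc[q] = wrap(V[cre[q]]);
    vout = vc;
  }
  return List::create(_["creator"] = wrap(cre), _["destroyer"] = wrap(des),
                      _["dim"] = wrap(credim), _["v"] = vout);
}

// ---------- on-the-fly birth cycles ----------

// Recursively rebuilds the reduction operations of the requested creator
// columns. Reduced columns R are re-derived on demand; a column's R is cached
// only once its computation has been requested more than cache_limit times
// (ops lists, which define the recursion, are always kept). The birth-cycle of
// creator j is the set of columns with odd path-parity in the ops DAG.
// owner_keys/owner_vals give the pivot bijection one dimension down:
// (d-1)-simplex filtration index -> its destroyer d-simplex index.
// [[Rcpp::export]]
List birth_cycles_cpp(IntegerMatrix verts, IntegerVector sdim,
                      NumericVector sdiam, int n, IntegerVector creators,
                      IntegerVector owner_keys, IntegerVector owner_vals,
                      int cache_limit) {
  FView f = make_view(verts, sdim, sdiam, n);
  std::unordered_map<u64, int> idx = build_index(f);
  std::unordered_map<int, int> owner;     // pivot -> destroyer column
  std::unordered_map<int, int> pivot_of;  // destroyer column -> its pivot
  for (int q = 0; q < owner_keys.size(); ++q) {
    owner[owner_keys[q]] = owner_vals[q];
    pivot_of[owner_vals[q]] = owner_keys[q];
  }
  std::unordered_map<int, Col> ops;     // always retained once derived
  std::unordered_map<int, Col> Rcache;  // selectively retained
  std::unordered_map<int, int> visits;

  struct Task {
    int j;
    Col c;
    Col myops;
    bool have_pending;
  };

  // iterative computation of R_j (and ops_j) with suspension on missing R_k
  std::vector<Task> st;
  Col last_result;

  std::function<void(int)> computeR = [&](int target) {
    Task t0;
    t0.j = target;
    t0.c = facets_of(f, idx, target);
    t0.have_pending = false;
    st.push_back(t0);
    while (!st.empty()) {
      Task& t = st.back();
      if (t.have_pending) {  // resume: XOR in the child's result
        t.c = xor_sorted(t.c, last_result);
        t.have_pending = false;
      }
      bool done = false;
      while (true) {
        if (t.c.empty()) { done = true; break; }
        int p = t.c.back();
        std::unordered_map<int, int>::iterator po = pivot_of.find(t.j);
        if (po != pivot_of.end() && p == po->second) { done = true; break; }
        std::unordered_map<int, int>::iterator ow = owner.find(p);
        if (ow == owner.end())
          stop("pivot without owner: persistence pairs inconsistent with filtration");
        int k = ow->second;
        t.myops.push_back(k);
        std::unordered_map<int, Col>::iterator rc = Rcache.find(k);
        if (rc != Rcache.end()) {
          t.c = xor_sorted(t.c, rc->second);
        } else {
          // need to (re)compute R_k first
          t.have_pending = true;
          Task tk;
          tk.j = k;
          tk.c = facets_of(f, idx, k);
          tk.have_pending = false;
          st.push_back(tk);
          done = false;
          break;
        }
      }
      if (!st.back().have_pending && !done) continue;  // descended into child
      if (done) {
        Task fin = st.back();
        st.pop_back();
        ops[fin.j] = fin.myops;
        int vis = ++visits[fin.j];
        if (vis > cache_limit) Rcache[fin.j] = fin.c;
        last_result = fin.c;
        if (!st.empty()) st.back().have_pending = true;
        // parent resumes on next loop iteration
      }
    }
  };

  // ensure ops exist for every column reachable from the creators
  std::function<void(int)> ensure_ops = [&](int j) {
    if (ops.count(j)) return;
    computeR(j);
  };

  List out(creators.size());
  for (int q = 0; q < creators.size(); ++q) {
    int c0 = creators[q];
    ensure_ops(c0);
    // breadth-first closure of the ops DAG, making sure all ops are derived
    std::vector<int> order;
    std::unordered_set<int> inq;
    std::vector<int> work;
    work.push_back(c0);
    inq.insert(c0);
    while (!work.empty()) {
      int j = work.back();
      work.pop_back();
      order.push_back(j);
      ensure_ops(j);
      const Col& oj = ops[j];
      for (size_t t = 0; t < oj.size(); ++t)
        if (inq.insert(oj[t]).second) work.push_back(oj[t]);
    }
    // path parity DP in decreasing filtration-index order (ops point downward)
    std::sort(order.begin(), order.end(), std::greater<int>());
    std::unordered_map<int, int> par;
    par[c0] = 1;
    Col cycle;
    for (size_t t = 0; t < order.size(); ++t) {
      int j = order[t];
      int pj = par.count(j) ? par[j] & 1 : 0;
      if (!pj) continue;
      cycle.push_back(j);
      const Col& oj = ops[j];
      for (size_t w = 0; w < oj.size(); ++w) par[oj[w]] ^= 1;
    }
    std::sort(cycle.begin(), cycle.end());
    out[q] = wrap(cycle);
  }
  return out;
}

// ---------- greedy shortening ----------

// Steepest-decrease greedy over pairwise Z2 additions. d* is the largest
// attainable length decrease |Ci| - |Ci xor Cj| over ordered pairs; while
// d* > 0, pairs achieving it are applied in ascending (i, j) order with
// immediate visibility. The optimized variant restricts the d* search to
// pairs sharing at least one simplex (other pairs cannot shorten), which is
// what makes the scan feasible for large H1 cycle sets.
// [[Rcpp::export]]
List greedy_shorten_cpp(List cycles_, bool optimized) {
  int k = cycles_.size();
  std::vector<Col> C(k);
  for (int i = 0; i < k; ++i) {
    IntegerVector ci = cycles_[i];
    C[i] = Col(ci.begin(), ci.end());
    std::sort(C[i].begin(), C[i].end());
  }
  std::vector<std::unordered_set<int> > S(k);
  for (int i = 0; i < k; ++i) S[i] = std::unordered_set<int>(C[i].begin(), C[i].end());

  auto dec_of = [&](int i, int j) {
    // decrease when replacing C_i by C_i xor C_j: 2|Ci ^ Cj| - |Cj|
    const Col& small = (C[i].size() < C[j].size()) ? C[i] : C[j];
    const std::unordered_set<int>& big = (C[i].size() < C[j].size()) ? S[j] : S[i];
    long inter = 0;
    for (size_t t = 0; t < small.size(); ++t) inter += big.count(small[t]);
    return 2 * inter - (long)C[j].size();
  };

  long n_passes = 0, n_applied = 0;
  while (true) {
    long dstar = 0;
    bool any = false;
    if (!optimized) {
      for (int i = 0; i < k; ++i)
        for (int j = 0; j < k; ++j) {
          if (i == j) continue;
          long d = dec_of(i, j);
          if (!any || d > dstar) { dstar = d; any = true; }
        }
    } else {
      // pairs sharing a simplex (others have decrease -|Cj| <= 0)
      std::unordered_map<int, std::vector<int> > where;
      for (int i = 0; i < k; ++i)
        for (size_t t = 0; t < C[i].size(); ++t) where[C[i][t]].push_back(i);
      std::set<std::pair<int, int> > cand;
      for (std::unordered_map<int, std::vector<int> >::iterator it = where.begin();
           it != where.end(); ++it) {
        std::vector<int>& v = it->second;
        for (size_t a = 0; a < v.size(); ++a)
          for (size_t b = a + 1; b < v.size(); ++b)
            cand.insert(std::make_pair(v[a], v[b]));
      }
      for (std::set<std::pair<int, int> >::iterator it = cand.begin();
           it != cand.end(); ++it) {
        long d1 = dec_of(it->first, it->second);
        long d2 = dec_of(it->second, it->first);
        long d = std::max(d1, d2);
        if (!any || d > dstar) { dstar = d; any = true; }
      }
      if (!any) dstar = 0;
    }
    if (!any || dstar <= 0) break;
    ++n_passes;
    for (int i = 0; i < k; ++i) {
      for (int j = 0; j < k; ++j) {
        if (i == j) continue;
        if (dec_of(i, j) == dstar) {
          C[i] = xor_sorted(C[i], C[j]);
          S[i] = std::unordered_set<int>(C[i].begin(), C[i].end());
          ++n_applied;
        }
      }
    }
  }
  List out(k);
  for (int i = 0; i < k; ++i) out[i] = wrap(C[i]);
  return List::create(_["cycles"] = out, _["n_passes"] = n_passes,
                      _["n_applied"] = n_applied);
}

// ---------- local smoothing ----------

// Reduce a d-cycle with boundaries of (d+1)-simplices of the complex that
// share a face with it; an XOR is applied when it strictly shortens the
// cycle, scanning candidate cofacets in filtration order until a fixed point.
// [[Rcpp::export]]
List smooth_cycles_cpp(IntegerMatrix verts, IntegerVector sdim,
                       NumericVector sdiam, int n, List cycles_) {
  FView f = make_view(verts, sdim, sdiam, n);
  std::unordered_map<u64, int> idx = build_index(f);
  std::vector<Col> adj = build_adj(f);
  int nc = cycles_.size();
  List out(nc);
  for (int q = 0; q < nc; ++q) {
    IntegerVector ci = cycles_[q];
    std::unordered_set<int> cyc(ci.begin(), ci.end());
    if (cyc.empty()) { out[q] = IntegerVector(0); continue; }
    int d = f.sdim(*cyc.begin());
    bool changed = true;
    while (changed) {
      changed = false;
      std::set<int> cands;
      for (std::unordered_set<int>::iterator it = cyc.begin(); it != cyc.end(); ++it) {
        Col cf = cofacets_of(f, idx, adj, *it);
        cands.insert(cf.begin(), cf.end());
      }
      for (std::set<int>::iterator it = cands.begin(); it != cands.end(); ++it) {
        Col fc = facets_of(f, idx, *it);
        int share = 0;
        for (size_t t = 0; t < fc.size(); ++t) share += cyc.count(fc[t]);
        if (2 * share > d + 2) {
          for (size_t t = 0; t < fc.size(); ++t) {
            if (cyc.count(fc[t])) cyc.erase(fc[t]);
            else cyc.insert(fc[t]);
          }
          changed = true;
        }
      }
    }
    Col res(cyc.begin(), cyc.end());
    std::sort(res.begin(), res.end());
    out[q] = wrap(res);
  }
  return out;
}

// ---------- chain boundary ----------

// Z2 boundary of a chain given as filtration indices.
// [[Rcpp::export]]
IntegerVector chain_boundary_cpp(IntegerMatrix verts, IntegerVector sdim,
                                 NumericVector sdiam, int n,
                                 IntegerVector chain) {
  FView f = make_view(verts, sdim, sdiam, n);
  std::unordered_map<u64, int> idx = build_index(f);
  std::unordered_map<int, int> parity;
  for (int q = 0; q < chain.size(); ++q) {
    Col fc = facets_of(f, idx, chain[q]);
    for (size_t t = 0; t < fc.size(); ++t) parity[fc[t]] ^= 1;
  }
  Col res;
  for (std::unordered_map<int, int>::iterator it = parity.begin();
       it != parity.end(); ++it)
    if (it->second) res.push_back(it->first);
  std::sort(res.begin(), res.end());
  return wrap(res);
}

// Facet indices of each listed simplex (one hash build for the whole batch).
// [[Rcpp::export]]
List facets_list_cpp(IntegerMatrix verts, IntegerVector sdim,
                     NumericVector sdiam, int n, IntegerVector idxs) {
  FView f = make_view(verts, sdim, sdiam, n);
  std::unordered_map<u64, int> idx = build_index(f);
  List out(idxs.size());
  for (int q = 0; q < idxs.size(); ++q) out[q] = wrap(facets_of(f, idx, idxs[q]));
  return out;
}

// Filtration index (0-based, -1 if absent) of each queried vertex tuple.
// [[Rcpp::export]]
IntegerVector simplex_index_cpp(IntegerMatrix verts, IntegerVector sdim,
                                NumericVector sdiam, int n,
                                IntegerMatrix query) {
  FView f = make_view(verts, sdim, sdiam, n);
  std::unordered_map<u64, int> idx = build_index(f);
  IntegerVector out(query.nrow());
  for (int q = 0; q < query.nrow(); ++q) {
    int vv[4];
    int nv = 0;
    for (int k = 0; k < query.ncol() && k < 4; ++k)
      if (query(q, k) >= 0) vv[nv++] = query(q, k);
    std::sort(vv, vv + nv);
    std::unordered_map<u64, int>::const_iterator it = idx.find(skey(vv, nv, f.B));
    out[q] = (it == idx.end()) ? -1 : it->second;
  }
  return out;
}

// Cofacet indices of a single simplex (used by the connectivity splitter and
// in tests).
// [[Rcpp::export]]
IntegerVector cofacets_cpp(IntegerMatrix verts, IntegerVector sdim,
                           NumericVector sdiam, int n, int i) {
  FView f = make_view(verts, sdim, sdiam, n);
  std::unordered_map<u64, int> idx = build_index(f);
  std::vector<Col> adj = build_adj(f);
  return wrap(cofacets_of(f, idx, adj, i));
}
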