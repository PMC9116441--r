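// Dimension-1 Vietoris-Rips persistence of a Euclidean point cloud.
//
// Persistent cohomology with clearing: dimension-0 pairs are found by a
// union-find pass over the edges; the remaining (cycle-creating) edges are
// reduced as coboundary columns in decreasing filtration order, with columns
// regenerated implicitly from the distance matrix.  Filtration values are
// pairwise distances ("diameter" scale).  The filtration is truncated at the
// enclosing radius min_p max_q d(p,q): at that value the complex is a cone,
// so every dimension-1 class has already died and no interval is lost.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <queue>
#include <unordered_map>
#include <vector>

using Rcpp::NumericMatrix;

namespace {

struct Entry {
  double diam;
  int64_t id;  // colex index of the sorted triple
};

// min-heap on the forward filtration order (diam asc, id asc):
// priority_queue pops the Compare-maximal element, so Compare must order
// "later in filtration" as larger.
struct EntryCmp {
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.diam != b.diam) return a.diam > b.diam;
    return a.id > b.id;
  }
};

inline int64_t tri_id(int64_t a, int64_t b, int64_t c) {
  // requires a < b < c
  return c * (c - 1) * (c - 2) / 6 + b * (b - 1) / 2 + a;
}

inline int64_t tri_id_sorted(int i, int j, int k) {
  int a = i, b = j, c = k;
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
  return tri_id(a, b, c);
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra == rb) return false;
    parent[ra] = rb;
    return true;
  }
};

struct Edge {
  double diam;
  int i, j;
};

class RipsH1 {
 public:
  RipsH1(const NumericMatrix& pts) : m_(pts.nrow()) {
    d_.assign(static_cast<size_t>(m_) * m_, 0.0);
    const int dim = pts.ncol();
    for (int i = 0; i < m_; ++i) {
      for (int j = i + 1; j < m_; ++j) {
        double s = 0.0;
        for (int c = 0; c < dim; ++c) {
          double dx = pts(i, c) - pts(j, c);
          s += dx * dx;
        }
        double dist = std::sqrt(s);
        d_[idx(i, j)] = dist;
        d_[idx(j, i)] = dist;
      }
    }
    // enclosing radius: beyond it the complex is a cone, H1 vanishes
    threshold_ = R_PosInf;
    for (int i = 0; i < m_; ++i) {
      double mx = 0.0;
      for (int j = 0; j < m_; ++j) mx = std::max(mx, d_[idx(i, j)]);
      threshold_ = std::min(threshold_, mx);
    }
  }

  NumericMatrix compute() {
    if (m_ < 3) return NumericMatrix(0, 2);
    assemble_columns();
    reduce();
    NumericMatrix out(static_cast<int>(births_.size()), 2);
    for (size_t r = 0; r < births_.size(); ++r) {
      out(static_cast<int>(r), 0) = births_[r];
      out(static_cast<int>(r), 1) = deaths_[r];
    }
    Rcpp::colnames(out) = Rcpp::CharacterVector::create("birth", "death");
    return out;
  }

 private:
  size_t idx(int i, int j) const {
    return static_cast<size_t>(i) * m_ + j;
  }
  int64_t edge_id(int i, int j) const {  // i < j
    return static_cast<int64_t>(j) * (j - 1) / 2 + i;
  }

  void assemble_columns() {
    std::vector<Edge> edges;
    edges.reserve(static_cast<size_t>(m_) * (m_ - 1) / 2);
    for (int j = 1; j < m_; ++j)
      for (int i = 0; i < j; ++i) {
        double dd = d_[idx(i, j)];
        if (dd <= threshold_) edges.push_back({dd, i, j});
      }
    // forward filtration order
    std::sort(edges.begin(), edges.end(), [this](const Edge& a, const Edge& b) {
      if (a.diam != b.diam) return a.diam < b.diam;
      return edge_id(a.i, a.j) < edge_id(b.i, b.j);
    });
    UnionFind uf(m_);
    columns_.clear();
    for (const Edge& e : edges)
      if (!uf.unite(e.i, e.j)) columns_.push_back(e);  // cycle-creating edge
    // process in reverse filtration order
    std::reverse(columns_.begin(), columns_.end());
  }

  // Enumerating k in increasing order enumerates cofacet triangle ids in
  // increasing colex order; any cofacet has diam >= the edge diam, so the
  // first cofacet found at equal diam is the column's pivot.
  template <typename F>
  void for_each_cofacet(const Edge& e, F&& f) const {
    for (int k = 0; k < m_; ++k) {
      if (k == e.i || k == e.j) continue;
      double dd = std::max(e.diam, std::max(d_[idx(e.i, k)], d_[idx(e.j, k)]));
      if (dd <= threshold_) f(dd, tri_id_sorted(e.i, e.j, k), k);
    }
  }

  void push_coboundary(const Edge& e,
                       std::priority_queue<Entry, std::vector<Entry>, EntryCmp>& heap) const {
    for_each_cofacet(e, [&](double dd, int64_t id, int) { heap.push({dd, id}); });
  }

  // lazy mod-2 cancellation: equal ids pop together and cancel in pairs
  static bool pop_pivot(std::priority_queue<Entry, std::vector<Entry>, EntryCmp>& heap,
                        Entry& pivot) {
    while (!heap.empty()) {
      Entry top = heap.top();
      heap.pop();
      int count = 1;
      while (!heap.empty() && heap.top().id == top.id) {
        heap.pop();
        ++count;
      }
      if (count % 2 == 1) {
        pivot = top;
        return true;
      }
    }
    return false;
  }

  void reduce() {
    std::unordered_map<int64_t, int> pivot_owner;  // triangle id -> column index
    pivot_owner.reserve(columns_.size() * 2);
    // V-matrix: for each reduced column, the other columns whose raw
    // coboundaries were added to it, so a later column can replay the
    // reduction without recursion.
    std::vector<std::vector<int>> vmat(columns_.size());
    for (int ci = 0; ci < static_cast<int>(columns_.size()); ++ci) {
      const Edge& e = columns_[ci];
      // emergent-pair shortcut: first cofacet at the edge's own diameter is
      // the pivot; if unclaimed, the pair has zero persistence and needs no
      // explicit reduction.
      int64_t shortcut = -1;
      for (int k = 0; k < m_ && shortcut < 0; ++k) {
        if (k == e.i || k == e.j) continue;
        if (std::max(d_[idx(e.i, k)], d_[idx(e.j, k)]) <= e.diam)
          shortcut = tri_id_sorted(e.i, e.j, k);
      }
      if (shortcut >= 0 && pivot_owner.find(shortcut) == pivot_owner.end()) {
        pivot_owner.emplace(shortcut, ci);
        continue;
      }
      std::priority_queue<Entry, std::vector<Entry>, EntryCmp> working;
      push_coboundary(e, working);
      std::vector<int> vcol;
      Entry pivot;
      while (true) {
        if (!pop_pivot(working, pivot)) break;  // essential: cannot occur below threshold
        auto it = pivot_owner.find(pivot.id);
        if (it == pivot_owner.end()) {
          pivot_owner.emplace(pivot.id, ci);
          if (pivot.diam > e.diam) {
            births_.push_back(e.diam);
            deaths_.push_back(pivot.diam);
          }
          break;
        }
        // the added column's reduced form has its minimum at the pivot, so
        // the pivot cancels against it and the working minimum increases
        working.push(pivot);
        const int cj = it->second;
        push_coboundary(columns_[cj], working);
        vcol.push_back(cj);
        for (int c : vmat[cj]) {
          push_coboundary(columns_[c], working);
          vcol.push_back(c);
        }
      }
      if (!vcol.empty()) {
        // store mod 2: repeated additions cancel, keeping replay columns short
        std::sort(vcol.begin(), vcol.end());
        std::vector<int> reduced;
        for (size_t a = 0; a < vcol.size();) {
          size_t b = a;
          while (b < vcol.size() && vcol[b] == vcol[a]) ++b;
          if ((b - a) % 2 == 1) reduced.push_back(vcol[a]);
          a = b;
        }
        vmat[ci] = std::move(reduced);
      }
    }
  }

  int m_;
  double threshold_;
  std::vector<double> d_;
  std::vector<Edge> columns_;
  std::vector<double> births_, deaths_;
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix rips_h1_cpp(NumericMatrix pts) {
  RipsH1 engine(pts);
  return engine.compute();
}
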