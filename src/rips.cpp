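#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Vietoris-Rips persistence over Z/2 by per-dimension boundary reduction.
// Dimension 0 uses union-find on the sorted edge list; dimensions 1 and 2
// reduce triangle (resp. tetrahedron) boundary columns with the standard
// pivot-claiming algorithm. Simplices are ordered by (filtration value,
// lexicographic vertex order); bar multisets are invariant to the tie-break.

namespace {

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

struct Edge { double len; int i, j; };
struct Tri  { double len; int i, j, k; };
struct Tet  { double len; int i, j, k, l; };

// symmetric difference of two ascending index vectors (Z/2 column addition)
void addColumn(std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  a.swap(out);
}

} // namespace

// [[Rcpp::export(name = ".rips_cpp")]]
DataFrame rips_cpp(NumericMatrix coords, double maxFiltration, int maxDim) {
  const int n = coords.nrow();
  if (n < 1) stop("point cloud must contain at least one point");
  if (maxDim < 0 || maxDim > 2) stop("maxDim must be 0, 1 or 2");
  const double F = maxFiltration;

  // pairwise distances
  std::vector<double> d((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i,0) - coords(j,0);
      double dy = coords(i,1) - coords(j,1);
      double dz = coords(i,2) - coords(j,2);
      double v = std::sqrt(dx*dx + dy*dy + dz*dz);
      d[(size_t)i * n + j] = v;
      d[(size_t)j * n + i] = v;
    }

  std::vector<Edge> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = d[(size_t)i * n + j];
      if (v <= F) edges.push_back({v, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.len != b.len) return a.len < b.len;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int nEdges = (int)edges.size();

  std::vector<int> barDim;
  std::vector<double> barBirth, barDeath;

  // ---- dimension 0: union-find ------------------------------------------
  UnionFind uf(n);
  std::vector<char> edgePositive(nEdges, 0); // 1 = creates a cycle
  int merges = 0;
  for (int e = 0; e < nEdges; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) {
      barDim.push_back(0);
      barBirth.push_back(0.0);
      barDeath.push_back(edges[e].len);
      ++merges;
    } else {
      edgePositive[e] = 1;
    }
  }
  for (int c = 0; c < n - merges; ++c) { // one infinite bar per component
    barDim.push_back(0);
    barBirth.push_back(0.0);
    barDeath.push_back(R_PosInf);
  }

  if (maxDim >= 1 && nEdges > 0) {
    // edge id lookup
    std::unordered_map<long long, int> edgeId;
    edgeId.reserve(edges.size() * 2);
    for (int e = 0; e < nEdges; ++e)
      edgeId[(long long)edges[e].i * n + edges[e].j] = e;

    // neighbour lists (ascending, only j > i kept where needed)
    std::vector<std::vector<int>> nbr(n);
    for (const Edge& e : edges) { nbr[e.i].push_back(e.j); }
    for (int i = 0; i < n; ++i) std::sort(nbr[i].begin(), nbr[i].end());

    // ---- triangles -------------------------------------------------------
    std::vector<Tri> tris;
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& Ni = nbr[i];
      for (size_t a = 0; a < Ni.size(); ++a)
        for (size_t b = a + 1; b < Ni.size(); ++b) {
          int j = Ni[a], k = Ni[b];
          double djk = d[(size_t)j * n + k];
          if (djk <= F) {
            double m = std::max({d[(size_t)i*n+j], d[(size_t)i*n+k], djk});
            tris.push_back({m, i, j, k});
          }
        }
    }
    std::sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
      if (a.len != b.len) return a.len < b.len;
      if (a.i != b.i) return a.i < b.i;
      if (a.j != b.j) return a.j < b.j;
      return a.k < b.k;
    });
    const int nTris = (int)tris.size();

    // reduce triangle columns over edge rows
    std::vector<int> pivotOwner(nEdges, -1);        // edge row -> column idx
    std::vector<std::vector<int>> reduced(nTris);
    std::vector<char> triPositive(nTris, 0);
    for (int t = 0; t < nTris; ++t) {
      std::vector<int> col = {
        edgeId[(long long)tris[t].i * n + tris[t].j],
        edgeId[(long long)tris[t].i * n + tris[t].k],
        edgeId[(long long)tris[t].j * n + tris[t].k]
      };
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int piv = col.back();
        int owner = pivotOwner[piv];
        if (owner < 0) {
          pivotOwner[piv] = t;
          double birth = edges[piv].len, death = tris[t].len;
          if (death > birth) {
            barDim.push_back(1);
            barBirth.push_back(birth);
            barDeath.push_back(death);
          }
          break;
        }
        addColumn(col, reduced[owner]);
      }
      if (col.empty()) triPositive[t] = 1;
      reduced[t].swap(col);
    }
    // unpaired cycle-creating edges: essential dim-1 classes
    for (int e = 0; e < nEdges; ++e)
      if (edgePositive[e] && pivotOwner[e] < 0) {
        barDim.push_back(1);
        barBirth.push_back(edges[e].len);
        barDeath.push_back(R_PosInf);
      }

    // ---- dimension 2: tetrahedra over triangles --------------------------
    if (maxDim >= 2 && nTris > 0) {
      std::unordered_map<long long, int> triId;
      triId.reserve(tris.size() * 2);
      for (int t = 0; t < nTris; ++t)
        triId[((long long)tris[t].i * n + tris[t].j) * n + tris[t].k] = t;

      std::vector<Tet> tets;
      for (int i = 0; i < n; ++i) {
        const std::vector<int>& Ni = nbr[i];
        for (size_t a = 0; a < Ni.size(); ++a)
          for (size_t b = a + 1; b < Ni.size(); ++b)
            for (size_t c = b + 1; c < Ni.size(); ++c) {
              int j = Ni[a], k = Ni[b], l = Ni[c];
              double djk = d[(size_t)j*n+k], djl = d[(size_t)j*n+l],
                     dkl = d[(size_t)k*n+l];
              if (djk <= F && djl <= F && dkl <= F) {
                double m = std::max({d[(size_t)i*n+j], d[(size_t)i*n+k],
                                     d[(size_t)i*n+l], djk, djl, dkl});
                tets.push_back({m, i, j, k, l});
              }
            }
      }
      std::sort(tets.begin(), tets.end(), [](const Tet& a, const Tet& b) {
        if (a.len != b.len) return a.len < b.len;
        if (a.i != b.i) return a.i < b.i;
        if (a.j != b.j) return a.j < b.j;
        if (a.k != b.k) return a.k < b.k;
        return a.l < b.l;
      });
      const int nTets = (int)tets.size();

      std::vector<int> triPivotOwner(nTris, -1);
      std::vector<std::vector<int>> reduced3(nTets);
      for (int t = 0; t < nTets; ++t) {
        int i = tets[t].i, j = tets[t].j, k = tets[t].k, l = tets[t].l;
        std::vector<int> col = {
          triId[((long long)i * n + j) * n + k],
          triId[((long long)i * n + j) * n + l],
          triId[((long long)i * n + k) * n + l],
          triId[((long long)j * n + k) * n + l]
        };
        std::sort(col.begin(), col.end());
        while (!col.empty()) {
          int piv = col.back();
          int owner = triPivotOwner[piv];
          if (owner < 0) {
            triPivotOwner[piv] = t;
            double birth = tris[piv].len, death = tets[t].len;
            if (death > birth) {
              barDim.push_back(2);
              barBirth.push_back(birth);
              barDeath.push_back(death);
            }
            break;
          }
          addColumn(col, reduced3[owner]);
        }
        reduced3[t].swap(col);
      }
      for (int t = 0; t < nTris; ++t)
        if (triPositive[t] && triPivotOwner[t] < 0) {
          barDim.push_back(2);
          barBirth.push_back(tris[t].len);
          barDeath.push_back(R_PosInf);
        }
    }
  }

  return DataFrame::create(_["dim"] = barDim,
                           _["birth"] = barBirth,
                           _["death"] = barDeath);
}
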