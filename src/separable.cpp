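#include <Rcpp.h>
using namespace Rcpp;

// Biedged-graph separability checks.
//
// Side vertices are numbered 2*i + s for node index i (0-based) and side s
// (0 = left, 1 = right). The biedged graph has an internal edge joining the
// two sides of every node, plus the adjacency edges supplied by the caller.
// A pair of sides (a, b) on distinct nodes is separable iff, after removing
// the internal edges of both boundary nodes, the component containing side a
// also contains side b but contains neither opposite boundary side.

struct SideGraph {
  int nnode;
  std::vector<std::vector<int>> adj;  // adjacency edges only (no internal)
};

static SideGraph build_side_graph(int nnode, const IntegerMatrix &edges) {
  SideGraph g;
  g.nnode = nnode;
  g.adj.assign(2 * nnode, {});
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = 2 * (edges(e, 0) - 1) + edges(e, 1);
    int v = 2 * (edges(e, 2) - 1) + edges(e, 3);
    g.adj[u].push_back(v);
    if (u != v) g.adj[v].push_back(u);
  }
  return g;
}

// BFS over the biedged graph with the internal edges of nodes cut_a and
// cut_b removed. Fills `seen`; returns false early if an opposite boundary
// side is reached (not separable).
static bool bfs_separable(const SideGraph &g, int a, int b,
                          std::vector<char> &seen, std::vector<int> &queue) {
  int cut_a = a / 2, cut_b = b / 2;
  int bad1 = a ^ 1, bad2 = b ^ 1;  // opposite sides of the boundary nodes
  std::fill(seen.begin(), seen.end(), 0);
  queue.clear();
  queue.push_back(a);
  seen[a] = 1;
  for (size_t qi = 0; qi < queue.size(); ++qi) {
    int u = queue[qi];
    // internal edge unless u's node is a cut node
    int un = u / 2;
    if (un != cut_a && un != cut_b) {
      int v = u ^ 1;
      if (!seen[v]) {
        if (v == bad1 || v == bad2) return false;
        seen[v] = 1; queue.push_back(v);
      }
    }
    for (int v : g.adj[u]) {
      if (!seen[v]) {
        if (v == bad1 || v == bad2) return false;
        seen[v] = 1; queue.push_back(v);
      }
    }
  }
  return seen[b] != 0;
}

// Test one side pair. Sides are (node 1-based, side 0/1).
// [[Rcpp::export]]
bool is_separable_cpp(int nnode, const IntegerMatrix &edges,
                      int a_node, int a_side, int b_node, int b_side) {
  SideGraph g = build_side_graph(nnode, edges);
  std::vector<char> seen(2 * nnode);
  std::vector<int> queue;
  queue.reserve(2 * nnode);
  int a = 2 * (a_node - 1) + a_side;
  int b = 2 * (b_node - 1) + b_side;
  return bfs_separable(g, a, b, seen, queue);
}

// Enumerate every separable side pair, with the interior node set of each.
// Returns a list with a 4-column matrix of pairs (a_node, a_side, b_node,
// b_side; canonical order a_node < b_node or (==, a_side <= b_side)) and a
// parallel list of interior node-id vectors (nodes strictly inside).
// [[Rcpp::export]]
List separable_pairs_cpp(int nnode, const IntegerMatrix &edges) {
  SideGraph g = build_side_graph(nnode, edges);
  std::vector<char> seen(2 * nnode);
  std::vector<int> queue;
  queue.reserve(2 * nnode);
  std::vector<int> rows;
  List interiors;
  for (int a = 0; a < 2 * nnode; ++a) {
    for (int b = a + 1; b < 2 * nnode; ++b) {
      if (a / 2 == b / 2) continue;  // same node: invalid pair
      if (bfs_separable(g, a, b, seen, queue)) {
        rows.push_back(a / 2 + 1); rows.push_back(a % 2);
        rows.push_back(b / 2 + 1); rows.push_back(b % 2);
        // interior: nodes with any seen side, excluding the boundary nodes
        std::vector<int> inter;
        for (int n = 0; n < nnode; ++n) {
          if (n == a / 2 || n == b / 2) continue;
          if (seen[2 * n] || seen[2 * n + 1]) inter.push_back(n + 1);
        }
        interiors.push_back(wrap(inter));
      }
    }
  }
  int np = (int)rows.size() / 4;
  IntegerMatrix pm(np, 4);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < 4; ++j) pm(i, j) = rows[4 * i + j];

  // minimality: pair i is minimal iff no side strictly inside its subgraph
  // is separable with either boundary. Index pairs by endpoint side.
  std::vector<std::vector<int>> by_side(2 * nnode);
  std::vector<int> sideA(np), sideB(np);
  for (int i = 0; i < np; ++i) {
    int a = 2 * (pm(i, 0) - 1) + pm(i, 1);
    int b = 2 * (pm(i, 2) - 1) + pm(i, 3);
    sideA[i] = a; sideB[i] = b;
    by_side[a].push_back(i);
    by_side[b].push_back(i);
  }
  LogicalVector minimal(np);
  std::vector<char> inside(nnode + 1, 0);
  for (int i = 0; i < np; ++i) {
    IntegerVector inter = interiors[i];
    for (int t = 0; t < inter.size(); ++t) inside[inter[t]] = 1;
    bool ok = true;
    for (int pass = 0; pass < 2 && ok; ++pass) {
      int s = pass == 0 ? sideA[i] : sideB[i];
      for (int j : by_side[s]) {
        if (j == i) continue;
        int other = (sideA[j] == s) ? sideB[j] : sideA[j];
        if (inside[other / 2 + 1]) { ok = false; break; }
      }
    }
    minimal[i] = ok;
    for (int t = 0; t < inter.size(); ++t) inside[inter[t]] = 0;
  }
  return List::create(_["pairs"] = pm, _["interiors"] = interiors,
                      _["minimal"] = minimal);
}
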