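#include <Rcpp.h>
#include <vector>
#include <climits>
#include <functional>
using namespace Rcpp;

// Binary-character Fitch score of an unrooted tree given as an edge list.
// Node ids are 0-based: leaves 0..nTaxa-1 (not all need be present in a
// partial tree), internal nodes from nTaxa upward. Leaf state sets are
// bitmasks over {0,1}: 1 = state 0, 2 = state 1, 3 = missing ('?').
// The tree is rooted at leaf 0 (which must be present); every node is then
// processed in postorder, combining child sets by intersection when
// non-empty, else union with one counted change. For two-state characters
// this sequential rule is exact also at multifurcations.
static int fitch_edges(const std::vector<int>& ea, const std::vector<int>& eb,
                       int nNodesMax, const IntegerMatrix& states, int nTaxa) {
  const int E = (int)ea.size();
  std::vector<std::vector<int>> adj(nNodesMax);
  for (int i = 0; i < E; ++i) {
    adj[ea[i]].push_back(eb[i]);
    adj[eb[i]].push_back(ea[i]);
  }
  // preorder from leaf 0; reversed it is a valid postorder
  std::vector<int> pre;
  pre.reserve(2 * nTaxa);
  std::vector<int> parent(nNodesMax, -1);
  std::vector<int> stack;
  stack.push_back(0);
  parent[0] = 0;  // sentinel: leaf 0 is its own parent
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    pre.push_back(v);
    for (int w : adj[v])
      if (w != parent[v] || (v == 0 && w == 0)) {
        parent[w] = v;
        stack.push_back(w);
      }
  }
  const int nChar = states.ncol();
  int cost = 0;
  std::vector<int> S(nNodesMax, 0);
  for (int c = 0; c < nChar; ++c) {
    for (int idx = (int)pre.size() - 1; idx >= 0; --idx) {
      int v = pre[idx];
      int s = 0;
      bool first = true;
      if (v < nTaxa) {  // leaf: own observed set seeds the combination
        s = states(v, c);
        first = false;
      }
      for (int w : adj[v]) {
        if (w == parent[v] && v != 0) continue;
        if (v == 0 && w == 0) continue;
        int cs = S[w];
        if (first) { s = cs; first = false; }
        else {
          int in = s & cs;
          if (in) s = in;
          else { s |= cs; ++cost; }
        }
      }
      S[v] = s;
    }
  }
  return cost;
}

// [[Rcpp::export(rng = false)]]
int fitch_score_cpp(IntegerMatrix edges, int nTaxa, IntegerMatrix states) {
  const int E = edges.nrow();
  std::vector<int> ea(E), eb(E);
  int mx = 0;
  for (int i = 0; i < E; ++i) {
    ea[i] = edges(i, 0);
    eb[i] = edges(i, 1);
    mx = std::max(mx, std::max(ea[i], eb[i]));
  }
  return fitch_edges(ea, eb, mx + 1, states, nTaxa);
}

// Exhaustive enumeration of unrooted binary topologies by stepwise leaf
// insertion, with branch-and-bound pruning (the Fitch score of a partial
// tree never decreases when a leaf is added). Returns every topology that
// attains the minimum total parsimony score, as 0-based edge matrices.
// [[Rcpp::export(rng = false)]]
List mp_exhaustive_cpp(IntegerMatrix states, int maxTrees = 1000000) {
  const int nTaxa = states.nrow();
  if (nTaxa < 4) stop("exhaustive search needs at least 4 taxa");
  const int nNodesMax = 2 * nTaxa - 1;
  std::vector<int> ea, eb;
  ea.reserve(2 * nTaxa);
  eb.reserve(2 * nTaxa);
  // initial tree: internal node nTaxa joins leaves 0, 1, 2
  ea.push_back(nTaxa); eb.push_back(0);
  ea.push_back(nTaxa); eb.push_back(1);
  ea.push_back(nTaxa); eb.push_back(2);

  int best = INT_MAX;
  bool truncated = false;
  std::vector<std::vector<int>> res_a, res_b;

  std::function<void(int)> rec = [&](int k) {
    int sc = fitch_edges(ea, eb, nNodesMax, states, nTaxa);
    if (sc > best) return;  // bound: adding leaves cannot lower the score
    if (k == nTaxa) {
      if (sc < best) {
        best = sc;
        res_a.clear();
        res_b.clear();
        truncated = false;
      }
      if ((int)res_a.size() < maxTrees) {
        res_a.push_back(ea);
        res_b.push_back(eb);
      } else truncated = true;
      return;
    }
    const int v = nTaxa + k - 2;  // internal node created for leaf k
    const int E = (int)ea.size();
    for (int i = 0; i < E; ++i) {
      int a = ea[i], b = eb[i];
      eb[i] = v;
      ea.push_back(v); eb.push_back(b);
      ea.push_back(v); eb.push_back(k);
      rec(k + 1);
      ea.pop_back(); eb.pop_back();
      ea.pop_back(); eb.pop_back();
      ea[i] = a; eb[i] = b;
    }
  };
  rec(3);

  List trees(res_a.size());
  for (size_t t = 0; t < res_a.size(); ++t) {
    IntegerMatrix m((int)res_a[t].size(), 2);
    for (size_t i = 0; i < res_a[t].size(); ++i) {
      m(i, 0) = res_a[t][i];
      m(i, 1) = res_b[t][i];
    }
    trees[t] = m;
  }
  return List::create(_["score"] = best, _["trees"] = trees,
                      _["truncated"] = truncated);
}
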