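#include <Rcpp.h>
using namespace Rcpp;

// Equal-rates-Markov (ERM / Yule) topology growth: repeatedly split a
// uniformly chosen extant lineage until n tips exist. Uses R's RNG so
// set.seed() governs reproducibility.

// [[Rcpp::export]]
IntegerMatrix erm_topology_edges(int n) {
  if (n < 2) stop("n must be >= 2");
  int n_nodes = 2 * n - 1;
  std::vector<int> left(n_nodes, -1), right(n_nodes, -1);
  std::vector<int> active;
  active.reserve(n);
  active.push_back(0);
  int next_id = 1;
  while ((int)active.size() < n) {
    int k = (int)active.size();
    int pick = (int)std::floor(unif_rand() * k);
    if (pick >= k) pick = k - 1;
    int node = active[pick];
    left[node] = next_id;
    right[node] = next_id + 1;
    active[pick] = next_id;
    active.push_back(next_id + 1);
    next_id += 2;
  }
  // assign ape ids: tips 1..n in preorder encounter order, internals n+1..
  std::vector<int> ape_id(n_nodes, 0);
  IntegerMatrix edge(2 * (n - 1), 2);
  int tip_ct = 0, int_ct = 0, row = 0;
  std::vector<int> stack;
  stack.push_back(0);
  // first pass: assign ids in preorder
  std::vector<int> order;
  order.reserve(n_nodes);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    if (left[v] >= 0) {
      ape_id[v] = n + 1 + int_ct++;
      stack.push_back(right[v]);
      stack.push_back(left[v]);
    } else {
      ape_id[v] = ++tip_ct;
    }
  }
  for (size_t i = 0; i < order.size(); ++i) {
    int v = order[i];
    if (left[v] >= 0) {
      edge(row, 0) = ape_id[v]; edge(row, 1) = ape_id[left[v]]; ++row;
      edge(row, 0) = ape_id[v]; edge(row, 1) = ape_id[right[v]]; ++row;
    }
  }
  return edge;
}

// Larger root-side tip count for nrep independent ERM trees of n tips:
// only side membership is tracked, the growth process is identical to
// erm_topology_edges.

// [[Rcpp::export]]
IntegerVector erm_root_larger_side(int n, int nrep) {
  if (n < 2) stop("n must be >= 2");
  IntegerVector out(nrep);
  std::vector<int> side;
  side.reserve(n);
  for (int r = 0; r < nrep; ++r) {
    side.clear();
    side.push_back(0);
    side.push_back(1);
    while ((int)side.size() < n) {
      int k = (int)side.size();
      int pick = (int)std::floor(unif_rand() * k);
      if (pick >= k) pick = k - 1;
      side.push_back(side[pick]);
    }
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += side[i];
    out[r] = std::max(n1, n - n1);
  }
  return out;
}
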