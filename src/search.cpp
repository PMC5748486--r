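// Exhaustive maximum-compatibility search over rooted binary topologies,
// plus the pattern scorer shared with the R-level hill climb.
//
// Topologies are generated by sequential leaf insertion: with k leaves
// placed there are 2k-1 nodes, hence 2k-1 edges (counting the trunk above
// the root), giving (2n-3)!! rooted binary leaf-labeled shapes.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct SearchState {
  int n;                       // number of tips
  std::vector<int> parent;     // size 2n-1; -1 = root
  int root;
  std::vector<unsigned> car, non;
  std::vector<double> w;
  std::vector<std::string> labels;
  double best_score;
  std::string best_newick;
  std::vector<unsigned> masks; // scratch, size 2n-1

  double score_current(int n_nodes) {
    std::fill(masks.begin(), masks.begin() + n_nodes, 0u);
    for (int tip = 0; tip < n; ++tip) {
      unsigned bit = 1u << tip;
      for (int x = tip; x != -1; x = parent[x]) masks[x] |= bit;
    }
    double s = 0.0;
    for (size_t j = 0; j < car.size(); ++j) {
      unsigned cj = car[j], nj = non[j];
      for (int v = 0; v < n_nodes; ++v) {
        if ((masks[v] & cj) == cj && (masks[v] & nj) == 0u) {
          s += w[j];
          break;
        }
      }
    }
    return s;
  }

  // canonical newick (children ordered by smallest tip label)
  std::pair<std::string, std::string> newick_node(
      int v, const std::vector<std::vector<int> >& kids) {
    if (kids[v].empty())
      return std::make_pair(labels[v], labels[v]);
    std::pair<std::string, std::string> a = newick_node(kids[v][0], kids);
    std::pair<std::string, std::string> b = newick_node(kids[v][1], kids);
    if (b.second < a.second) std::swap(a, b);
    return std::make_pair("(" + a.first + "," + b.first + ")", a.second);
  }

  std::string canonical_newick(int n_nodes) {
    std::vector<std::vector<int> > kids(n_nodes);
    int rt = -1;
    for (int v = 0; v < n_nodes; ++v) {
      if (parent[v] == -1) rt = v;
      else kids[parent[v]].push_back(v);
    }
    return newick_node(rt, kids).first + ";";
  }

  void consider(int n_nodes) {
    double s = score_current(n_nodes);
    if (s < best_score) return;
    std::string nwk = canonical_newick(n_nodes);
    if (s > best_score || nwk < best_newick) {
      best_score = s;
      best_newick = nwk;
    }
  }

  // insert tip k (0-based) on every edge; internal node for this step is
  // n + k - 1
  void recurse(int k) {
    if (k == n) {
      consider(2 * n - 1);
      return;
    }
    int newint = n + k - 1;
    int n_active = 2 * k - 1; // k tips + k-1 internals placed so far
    for (int a = 0; a < n_active; ++a) {
      int x = (a < k) ? a : n + (a - k); // tips 0..k-1, internals n..n+k-2
      int oldp = parent[x];
      parent[newint] = oldp;
      parent[x] = newint;
      parent[k] = newint;
      recurse(k + 1);
      parent[x] = oldp;
    }
    parent[newint] = -1;
    parent[k] = -1;
  }
};

}  // namespace

// [[Rcpp::export]]
double score_patterns_cpp(IntegerVector clade_masks, IntegerVector car,
                          IntegerVector non, NumericVector w) {
  double s = 0.0;
  int n_nodes = clade_masks.size();
  for (int j = 0; j < car.size(); ++j) {
    unsigned cj = (unsigned)car[j], nj = (unsigned)non[j];
    for (int v = 0; v < n_nodes; ++v) {
      unsigned m = (unsigned)clade_masks[v];
      if ((m & cj) == cj && (m & nj) == 0u) {
        s += w[j];
        break;
      }
    }
  }
  return s;
}

// [[Rcpp::export]]
List exhaustive_search_cpp(int n_tip, IntegerVector car, IntegerVector non,
                           NumericVector w, CharacterVector labels) {
  if (n_tip < 2) stop("need at least 2 tips");
  if (n_tip > 12) stop("exhaustive search limited to 12 tips");
  SearchState st;
  st.n = n_tip;
  st.parent.assign(2 * n_tip - 1, -1);
  st.masks.assign(2 * n_tip - 1, 0u);
  st.car.assign(car.begin(), car.end());
  st.non.assign(non.begin(), non.end());
  st.w.assign(w.begin(), w.end());
  for (int i = 0; i < n_tip; ++i)
    st.labels.push_back(as<std::string>(labels[i]));
  st.best_score = -1.0;
  // initial 2-tip tree: tips 0,1 under internal n_tip
  st.parent[0] = st.parent[1] = n_tip;
  st.parent[n_tip] = -1;
  st.recurse(2);
  return List::create(_["score"] = st.best_score,
                      _["newick"] = st.best_newick);
}
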