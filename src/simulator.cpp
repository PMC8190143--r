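#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Gillespie simulation of a gene family syntenic network along a rooted,
// dated species tree. Genes duplicate (rate lambda), are lost (rate mu) and
// rearrange (rate nu) per gene per unit branch length (100 My). A
// duplication copies each syntenic edge of the parent gene to the new copy
// with probability p_dup; a rearrangement deletes each incident edge with
// probability p_rea; a loss deletes the gene with its edges. At a
// speciation every extant gene is copied into both daughter branches, all
// existing edges (within the branch and to other lineages) are inherited by
// both copies, and one new cross edge joins the two copies of the same
// parent gene. Branches are processed in preorder. Root gene count is
// 1 + Geometric(p_root) (support {1, 2, ...}, mean 1/p_root). Root genes
// start unlinked unless root_complete is true.
//
// Uses R's RNG: results are reproducible under set.seed().

struct FamState {
  std::vector<int> branch;            // branch (node id) holding each gene
  std::vector<char> alive;
  std::vector<std::vector<int>> adj;  // adjacency among alive genes

  int new_gene(int node) {
    branch.push_back(node);
    alive.push_back(1);
    adj.push_back(std::vector<int>());
    return static_cast<int>(branch.size()) - 1;
  }
  void add_edge(int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  void remove_edge(int a, int b) {
    auto ita = std::find(adj[a].begin(), adj[a].end(), b);
    if (ita != adj[a].end()) adj[a].erase(ita);
    auto itb = std::find(adj[b].begin(), adj[b].end(), a);
    if (itb != adj[b].end()) adj[b].erase(itb);
  }
  void kill(int g) {
    std::vector<int> nb = adj[g];
    for (int x : nb) remove_edge(g, x);
    alive[g] = 0;
  }
};

static void simulate_branch(FamState& st, std::vector<int>& cur, double T,
                            int node, double lambda, double mu, double nu,
                            double p_dup, double p_rea) {
  const double per_gene = lambda + mu + nu;
  if (per_gene <= 0.0 || T <= 0.0) return;
  double t = 0.0;
  while (!cur.empty()) {
    const double total = per_gene * cur.size();
    t += R::exp_rand() / total;
    if (t > T) break;
    const double u = R::unif_rand() * per_gene;
    int j = static_cast<int>(R::unif_rand() * cur.size());
    if (j >= static_cast<int>(cur.size())) j = cur.size() - 1;
    const int g = cur[j];
    if (u < lambda) {  // duplication
      const int nw = st.new_gene(node);
      std::vector<int> nb = st.adj[g];
      for (int x : nb) {
        if (R::unif_rand() < p_dup) st.add_edge(nw, x);
      }
      cur.push_back(nw);
    } else if (u < lambda + mu) {  // loss
      st.kill(g);
      cur.erase(cur.begin() + j);
    } else {  // rearrangement
      std::vector<int> nb = st.adj[g];
      for (int x : nb) {
        if (R::unif_rand() < p_rea) st.remove_edge(g, x);
      }
    }
  }
}

// preorder recursion; children[node] holds 0, or the two daughter nodes
static void process_node(FamState& st, std::vector<int> cur, int node,
                         const std::vector<int>& child1,
                         const std::vector<int>& child2,
                         const std::vector<double>& blen, double lambda,
                         double mu, double nu, double p_dup, double p_rea) {
  simulate_branch(st, cur, blen[node], node, lambda, mu, nu, p_dup, p_rea);
  if (child1[node] < 0) return;  // tip: survivors stay assigned to the leaf
  const int c1 = child1[node], c2 = child2[node];
  const int n_cur = static_cast<int>(cur.size());
  std::vector<int> copy1(n_cur), copy2(n_cur);
  std::vector<int> pos(st.branch.size(), -1);
  for (int i = 0; i < n_cur; ++i) pos[cur[i]] = i;
  for (int i = 0; i < n_cur; ++i) {
    copy1[i] = st.new_gene(c1);
    copy2[i] = st.new_gene(c2);
  }
  for (int i = 0; i < n_cur; ++i) {
    const int g = cur[i];
    for (int x : st.adj[g]) {
      const int ix = (x < static_cast<int>(pos.size())) ? pos[x] : -1;
      if (ix >= 0) {  // within-branch edge, add once per unordered pair
        if (ix > i) {
          st.add_edge(copy1[i], copy1[ix]);
          st.add_edge(copy2[i], copy2[ix]);
        }
      } else {  // edge to another lineage, inherited by both copies
        st.add_edge(copy1[i], x);
        st.add_edge(copy2[i], x);
      }
    }
    st.add_edge(copy1[i], copy2[i]);
  }
  for (int i = 0; i < n_cur; ++i) st.kill(cur[i]);
  std::vector<int> cur1(copy1), cur2(copy2);
  process_node(st, cur1, c1, child1, child2, blen, lambda, mu, nu, p_dup,
               p_rea);
  process_node(st, cur2, c2, child1, child2, blen, lambda, mu, nu, p_dup,
               p_rea);
}

static FamState simulate_family_core(const std::vector<int>& child1,
                                     const std::vector<int>& child2,
                                     const std::vector<double>& blen,
                                     int root, double lambda, double mu,
                                     double nu, double p_dup, double p_rea,
                                     double p_root, bool root_complete) {
  FamState st;
  int n0 = 1 + static_cast<int>(R::rgeom(p_root));
  std::vector<int> cur;
  for (int i = 0; i < n0; ++i) cur.push_back(st.new_gene(root));
  if (root_complete) {
    for (int i = 0; i < n0; ++i) {
      for (int j = i + 1; j < n0; ++j) st.add_edge(cur[i], cur[j]);
    }
  }
  process_node(st, cur, root, child1, child2, blen, lambda, mu, nu, p_dup,
               p_rea);
  return st;
}

static void tree_arrays(const IntegerMatrix& edge,
                        const NumericVector& edge_length, int n_node,
                        std::vector<int>& child1, std::vector<int>& child2,
                        std::vector<double>& blen) {
  child1.assign(n_node + 1, -1);
  child2.assign(n_node + 1, -1);
  blen.assign(n_node + 1, 0.0);
  for (int e = 0; e < edge.nrow(); ++e) {
    const int p = edge(e, 0), ch = edge(e, 1);
    blen[ch] = edge_length[e];
    if (child1[p] < 0) {
      child1[p] = ch;
    } else if (child2[p] < 0) {
      child2[p] = ch;
    } else {
      stop("species tree must be binary");
    }
  }
  for (int v = 1; v <= n_node; ++v) {
    if ((child1[v] < 0) != (child2[v] < 0)) {
      stop("species tree must be binary");
    }
  }
}

// [[Rcpp::export(name = ".sim_family_cpp")]]
List sim_family_cpp(const IntegerMatrix& edge,
                    const NumericVector& edge_length, int n_tip, int n_node,
                    int root, double lambda, double mu, double nu,
                    double p_dup, double p_rea, double p_root,
                    bool root_complete) {
  std::vector<int> child1, child2;
  std::vector<double> blen;
  tree_arrays(edge, edge_length, n_node, child1, child2, blen);
  FamState st = simulate_family_core(child1, child2, blen, root, lambda, mu,
                                     nu, p_dup, p_rea, p_root, root_complete);
  std::vector<int> ids, species;
  const int ng = static_cast<int>(st.branch.size());
  std::vector<int> newid(ng, -1);
  for (int g = 0; g < ng; ++g) {
    if (st.alive[g] && st.branch[g] <= n_tip) {
      newid[g] = static_cast<int>(ids.size());
      ids.push_back(g + 1);
      species.push_back(st.branch[g]);
    }
  }
  std::vector<int> ea, eb;
  for (int g = 0; g < ng; ++g) {
    if (newid[g] < 0) continue;
    for (int x : st.adj[g]) {
      if (x > g && newid[x] >= 0) {
        ea.push_back(g + 1);
        eb.push_back(x + 1);
      }
    }
  }
  IntegerMatrix edges(static_cast<int>(ea.size()), 2);
  for (size_t i = 0; i < ea.size(); ++i) {
    edges(static_cast<int>(i), 0) = ea[i];
    edges(static_cast<int>(i), 1) = eb[i];
  }
  return List::create(_["gene"] = wrap(ids), _["species"] = wrap(species),
                      _["edges"] = edges);
}

// union-find
static int uf_find(std::vector<int>& up, int x) {
  while (up[x] != x) {
    up[x] = up[up[x]];
    x = up[x];
  }
  return x;
}

// Simulates n_families independent families and returns the per-species
// gene counts of every synteny cluster (connected component of size >= 2
// among extant leaf genes) as an n_tip x n_clusters integer matrix.
// [[Rcpp::export(name = ".sim_dataset_cpp")]]
IntegerMatrix sim_dataset_cpp(const IntegerMatrix& edge,
                              const NumericVector& edge_length, int n_tip,
                              int n_node, int root, double lambda, double mu,
                              double nu, double p_dup, double p_rea,
                              double p_root, bool root_complete,
                              int n_families) {
  std::vector<int> child1, child2;
  std::vector<double> blen;
  tree_arrays(edge, edge_length, n_node, child1, child2, blen);
  std::vector<std::vector<int>> columns;  // each of length n_tip
  for (int fam = 0; fam < n_families; ++fam) {
    FamState st = simulate_family_core(child1, child2, blen, root, lambda,
                                       mu, nu, p_dup, p_rea, p_root,
                                       root_complete);
    const int ng = static_cast<int>(st.branch.size());
    std::vector<char> extant(ng, 0);
    for (int g = 0; g < ng; ++g) {
      extant[g] = st.alive[g] && st.branch[g] <= n_tip;
    }
    std::vector<int> up(ng);
    for (int g = 0; g < ng; ++g) up[g] = g;
    for (int g = 0; g < ng; ++g) {
      if (!extant[g]) continue;
      for (int x : st.adj[g]) {
        if (x > g && extant[x]) up[uf_find(up, x)] = uf_find(up, g);
      }
    }
    std::vector<int> comp_col(ng, -1), comp_size(ng, 0);
    for (int g = 0; g < ng; ++g) {
      if (extant[g]) ++comp_size[uf_find(up, g)];
    }
    for (int g = 0; g < ng; ++g) {
      if (!extant[g]) continue;
      const int r = uf_find(up, g);
      if (comp_size[r] < 2) continue;
      if (comp_col[r] < 0) {
        comp_col[r] = static_cast<int>(columns.size());
        columns.push_back(std::vector<int>(n_tip, 0));
      }
      ++columns[comp_col[r]][st.branch[g] - 1];
    }
  }
  IntegerMatrix out(n_tip, static_cast<int>(columns.size()));
  for (size_t c = 0; c < columns.size(); ++c) {
    for (int i = 0; i < n_tip; ++i) {
      out(i, static_cast<int>(c)) = columns[c][i];
    }
  }
  return out;
}
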