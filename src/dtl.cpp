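// Undated parsimony DTL reconciliation, formulation with unrooted extension.
//
// Dynamic programme over (gene node g, species node s):
//   c(g,s)  : minimum cost of the subtree of g with g mapped exactly at s
//   in(g,s) : min(c(g,s), min_{s_c child of s} in(g,s_c) + C_L)
//   d(g,s)  : min_{s' in subtree(s)} c(g,s')
//   out(g,s): min_{s' incomparable to s} c(g,s')
// Internal g with children a,b:
//   c(g,s) = min( speciation, duplication + C_D, transfer + C_T )
// Optimum = min_s c(root(g), s).  Infinite costs (TL mode) propagate as
// IEEE +Inf; no subtraction is ever performed on them.

#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

namespace {

struct SpeciesTree {
  int n;                      // number of nodes
  std::vector<int> kid1, kid2;  // -1 for leaves
  std::vector<int> post;        // postorder node sequence (children first)
  bool leaf(int s) const { return kid1[s] < 0; }
};

// One row set of DP vectors for a single gene node.
struct Rows {
  std::vector<double> c, in, d, out;
};

void fill_rows(Rows &r, const SpeciesTree &S, double cl) {
  const int n = S.n;
  r.in.assign(n, 0.0);
  r.d.assign(n, 0.0);
  r.out.assign(n, INF);
  for (int k = 0; k < n; ++k) {
    int s = S.post[k];
    if (S.leaf(s)) {
      r.in[s] = r.c[s];
      r.d[s] = r.c[s];
    } else {
      int s1 = S.kid1[s], s2 = S.kid2[s];
      r.in[s] = std::min(r.c[s], std::min(r.in[s1], r.in[s2]) + cl);
      r.d[s] = std::min(r.c[s], std::min(r.d[s1], r.d[s2]));
    }
  }
  // preorder = reverse postorder
  for (int k = n - 1; k >= 0; --k) {
    int s = S.post[k];
    if (!S.leaf(s)) {
      int s1 = S.kid1[s], s2 = S.kid2[s];
      r.out[s1] = std::min(r.out[s], r.d[s2]);
      r.out[s2] = std::min(r.out[s], r.d[s1]);
    }
  }
}

void gene_node_c(Rows &r, const Rows &ra, const Rows &rb, const SpeciesTree &S,
                 double cd, double ct) {
  const int n = S.n;
  r.c.assign(n, INF);
  for (int s = 0; s < n; ++s) {
    double best = INF;
    if (!S.leaf(s)) {
      int s1 = S.kid1[s], s2 = S.kid2[s];
      double spec = std::min(ra.in[s1] + rb.in[s2], ra.in[s2] + rb.in[s1]);
      if (spec < best) best = spec;
    }
    double dup = ra.in[s] + rb.in[s] + cd;
    if (dup < best) best = dup;
    double tr = std::min(ra.in[s] + rb.out[s], rb.in[s] + ra.out[s]) + ct;
    if (tr < best) best = tr;
    r.c[s] = best;
  }
}

SpeciesTree make_species(const IntegerMatrix &skids, const IntegerVector &spost) {
  SpeciesTree S;
  S.n = skids.nrow();
  S.kid1.resize(S.n);
  S.kid2.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.kid1[i] = skids(i, 0);
    S.kid2[i] = skids(i, 1);
  }
  S.post.assign(spost.begin(), spost.end());
  return S;
}

} // namespace

// Rooted DP. gkids: (#gene nodes) x 2 child ids, -1 for leaves; gpost:
// postorder gene node sequence; gleaf_sp: species node image per gene leaf
// (-1 for internal). All indices 0-based. Returns the optimal cost and,
// when tables = TRUE, the full c/in/out matrices for backtracking.
// [[Rcpp::export(name = ".dtl_dp_rooted")]]
List dtl_dp_rooted(IntegerMatrix gkids, IntegerVector gpost,
                   IntegerVector gleaf_sp, IntegerMatrix skids,
                   IntegerVector spost, double cd, double ct, double cl,
                   bool tables) {
  SpeciesTree S = make_species(skids, spost);
  const int ng = gkids.nrow(), n = S.n;
  std::vector<Rows> rows(ng);
  for (int k = 0; k < ng; ++k) {
    int g = gpost[k];
    Rows &r = rows[g];
    if (gkids(g, 0) < 0) {
      r.c.assign(n, INF);
      r.c[gleaf_sp[g]] = 0.0;
    } else {
      gene_node_c(r, rows[gkids(g, 0)], rows[gkids(g, 1)], S, cd, ct);
    }
    fill_rows(r, S, cl);
  }
  int groot = gpost[ng - 1];
  double best = INF;
  for (int s = 0; s < n; ++s) best = std::min(best, rows[groot].c[s]);
  List res = List::create(_["cost"] = best);
  if (tables) {
    NumericMatrix C(ng, n), IN(ng, n), OUT(ng, n);
    for (int g = 0; g < ng; ++g)
      for (int s = 0; s < n; ++s) {
        C(g, s) = rows[g].c[s];
        IN(g, s) = rows[g].in[s];
        OUT(g, s) = rows[g].out[s];
      }
    res["C"] = C;
    res["IN"] = IN;
    res["OUT"] = OUT;
  }
  return res;
}

// 64-bit FNV-1a hash of a string, as a hex string: compact cache keys for
// canonical topology strings (which can exceed R's symbol-length limit).
// [[Rcpp::export(name = ".str_hash")]]
std::string str_hash(std::string s) {
  uint64_t h = 1469598103934665603ULL;
  for (unsigned char c : s) {
    h ^= c;
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// Unrooted gene tree: run the rooted DP for every rooting (one per edge of
// the unrooted topology) and report all costs. edges: edge matrix of the
// unrooted tree (0-based node ids, any orientation), ntip tips numbered
// 0..ntip-1, tip_sp their species images. Ties favour the smallest edge
// index, which makes the optimal rooting deterministic.
// [[Rcpp::export(name = ".dtl_dp_unrooted")]]
List dtl_dp_unrooted(IntegerMatrix edges, int ntip, IntegerVector tip_sp,
                     IntegerMatrix skids, IntegerVector spost, double cd,
                     double ct, double cl) {
  SpeciesTree S = make_species(skids, spost);
  const int ne = edges.nrow();
  int nnode = 0;
  for (int e = 0; e < ne; ++e)
    nnode = std::max(nnode, std::max(edges(e, 0), edges(e, 1)) + 1);
  // adjacency
  std::vector<std::vector<int>> adj(nnode);
  for (int e = 0; e < ne; ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  const int ng = nnode + 1; // + virtual root
  const int vroot = nnode;
  NumericVector costs(ne);
  double best = INF;
  int best_edge = -1;

  std::vector<int> kid1(ng), kid2(ng), post(ng), stack(ng), par(ng);
  for (int e = 0; e < ne; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    // orient away from virtual root placed on edge (u,v)
    std::fill(kid1.begin(), kid1.end(), -1);
    std::fill(kid2.begin(), kid2.end(), -1);
    kid1[vroot] = u;
    kid2[vroot] = v;
    par[u] = vroot;
    par[v] = vroot;
    int top = 0, np = 0;
    stack[top++] = u;
    stack[top++] = v;
    std::vector<int> order;
    order.reserve(ng);
    while (top > 0) {
      int x = stack[--top];
      order.push_back(x);
      int nk = 0;
      for (int y : adj[x]) {
        if (y == par[x]) continue;
        // skip the rooted edge's counterpart
        if ((x == u && y == v) || (x == v && y == u)) continue;
        par[y] = x;
        if (nk == 0) kid1[x] = y; else kid2[x] = y;
        ++nk;
        stack[top++] = y;
      }
    }
    // postorder = reverse preorder (children pushed after parent)
    np = (int)order.size();
    IntegerVector gpost(np + 1);
    for (int i = 0; i < np; ++i) gpost[i] = order[np - 1 - i];
    gpost[np] = vroot;

    IntegerMatrix gk(ng, 2);
    IntegerVector gl(ng);
    for (int i = 0; i < ng; ++i) {
      gk(i, 0) = kid1[i];
      gk(i, 1) = kid2[i];
      gl[i] = (i < ntip) ? tip_sp[i] : -1;
    }
    List r = dtl_dp_rooted(gk, gpost, gl, skids, spost, cd, ct, cl, false);
    double cost = as<double>(r["cost"]);
    costs[e] = cost;
    if (cost < best) {
      best = cost;
      best_edge = e;
    }
  }
  return List::create(_["costs"] = costs, _["best_edge"] = best_edge + 1,
                      _["best_cost"] = best);
}
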