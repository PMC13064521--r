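// Progressive partial-order alignment (POA).
//
// The graph is initialised from the first sequence (the local reference) as a
// linear chain; each subsequent sequence is aligned to the graph by global
// sequence-to-DAG dynamic programming with affine gaps (a gap of length L
// costs open + ext * L) and fused into it. Nodes aligned to one another share
// an "alignment ring"; rings become MSA columns. For a single added sequence
// against the initial chain the DP is exactly global Needleman-Wunsch, which
// is the invariant the R test suite checks against an independent
// implementation.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <queue>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

struct PoaGraph {
  std::vector<char> base;
  std::vector<std::vector<int> > preds, succs;
  std::vector<int> ring;                    // ring id per node
  std::vector<std::vector<int> > ring_nodes;

  int add_node(char b, int ring_id) {
    base.push_back(b);
    preds.push_back(std::vector<int>());
    succs.push_back(std::vector<int>());
    if (ring_id < 0) {
      ring_id = (int)ring_nodes.size();
      ring_nodes.push_back(std::vector<int>());
    }
    ring.push_back(ring_id);
    ring_nodes[ring_id].push_back((int)base.size() - 1);
    return (int)base.size() - 1;
  }

  void add_edge(int u, int v) {
    for (size_t i = 0; i < succs[u].size(); ++i)
      if (succs[u][i] == v) return;
    succs[u].push_back(v);
    preds[v].push_back(u);
  }

  std::vector<int> topo_order() const {
    int n = (int)base.size();
    std::vector<int> indeg(n, 0);
    for (int v = 0; v < n; ++v) indeg[v] = (int)preds[v].size();
    std::priority_queue<int, std::vector<int>, std::greater<int> > q;
    for (int v = 0; v < n; ++v) if (indeg[v] == 0) q.push(v);
    std::vector<int> order;
    order.reserve(n);
    while (!q.empty()) {
      int v = q.top(); q.pop();
      order.push_back(v);
      for (size_t i = 0; i < succs[v].size(); ++i) {
        int w = succs[v][i];
        if (--indeg[w] == 0) q.push(w);
      }
    }
    if ((int)order.size() != n) stop("POA graph is not acyclic");
    return order;
  }
};

enum OpState { ST_M = 0, ST_D = 1, ST_I = 2, ST_START = 3 };

struct AlignResult {
  double score;
  // ops as (state, node, qpos): M consumes node+query, D node only,
  // I query only. 0-based qpos; node = graph node id (-1 for I).
  std::vector<int> op_state, op_node, op_qpos;
};

AlignResult align_to_graph(const PoaGraph &g, const std::string &q,
                           double match, double mismatch, double open,
                           double ext) {
  int n = (int)g.base.size();
  int m = (int)q.size();
  std::vector<int> order = g.topo_order();
  std::vector<int> tindex(n, -1);  // node -> topo position (1-based rows)
  for (int i = 0; i < n; ++i) tindex[order[i]] = i + 1;

  int rows = n + 1, cols = m + 1;
  std::vector<double> M((size_t)rows * cols, NEG_INF),
      D((size_t)rows * cols, NEG_INF), I((size_t)rows * cols, NEG_INF);
  // backpointers: previous row (topo index) and previous state
  std::vector<int> pM((size_t)rows * cols, -1), pD((size_t)rows * cols, -1),
      pI((size_t)rows * cols, -1);
  std::vector<signed char> sM((size_t)rows * cols, -1),
      sD((size_t)rows * cols, -1), sI((size_t)rows * cols, -1);

  const size_t C = (size_t)cols;
  auto idx = [C](int i, int j) { return (size_t)i * C + (size_t)j; };

  // virtual start row 0
  M[idx(0, 0)] = 0.0;
  sM[idx(0, 0)] = ST_START;
  for (int j = 1; j <= m; ++j) {
    double o = (j == 1) ? M[idx(0, 0)] - open - ext : I[idx(0, j - 1)] - ext;
    I[idx(0, j)] = o;
    pI[idx(0, j)] = 0;
    sI[idx(0, j)] = (j == 1) ? ST_M : ST_I;
  }

  for (int t = 0; t < n; ++t) {
    int v = order[t];
    int i = t + 1;
    std::vector<int> ps = g.preds[v];
    std::sort(ps.begin(), ps.end());
    std::vector<int> prows;
    if (ps.empty()) {
      prows.push_back(0);
    } else {
      for (size_t a = 0; a < ps.size(); ++a) prows.push_back(tindex[ps[a]]);
    }
    for (int j = 0; j <= m; ++j) {
      size_t here = idx(i, j);
      // M: align node v with q[j-1]
      if (j >= 1) {
        double sub = (g.base[v] == q[(size_t)j - 1]) ? match : mismatch;
        double best = NEG_INF; int bp = -1; signed char bs = -1;
        for (size_t a = 0; a < prows.size(); ++a) {
          size_t u = idx(prows[a], j - 1);
          const double cand[3] = {M[u], D[u], I[u]};
          for (int s = 0; s < 3; ++s) {
            if (cand[s] > best) { best = cand[s]; bp = prows[a]; bs = (signed char)s; }
          }
        }
        if (best > NEG_INF) {
          M[here] = best + sub; pM[here] = bp; sM[here] = bs;
        }
      }
      // D: consume node v with a gap in the query
      {
        double best = NEG_INF; int bp = -1; signed char bs = -1;
        for (size_t a = 0; a < prows.size(); ++a) {
          if (prows[a] == 0) {
            // deletion opening from the virtual start (leading node gap),
            // possibly after a leading query insertion
            if (j == 0) {
              double c = M[idx(0, 0)] - open - ext;
              if (c > best) { best = c; bp = 0; bs = ST_M; }
            } else {
              double c = I[idx(0, j)] - open - ext;
              if (c > best) { best = c; bp = 0; bs = ST_I; }
            }
            continue;
          }
          size_t u = idx(prows[a], j);
          double c;
          c = M[u] - open - ext;
          if (c > best) { best = c; bp = prows[a]; bs = ST_M; }
          c = D[u] - ext;
          if (c > best) { best = c; bp = prows[a]; bs = ST_D; }
          c = I[u] - open - ext;
          if (c > best) { best = c; bp = prows[a]; bs = ST_I; }
        }
        if (best > NEG_INF) { D[here] = best; pD[here] = bp; sD[here] = bs; }
      }
      // I: consume q[j-1] with a gap in the graph
      if (j >= 1) {
        size_t u = idx(i, j - 1);
        double best = M[u] - open - ext; signed char bs = ST_M;
        if (D[u] - open - ext > best) { best = D[u] - open - ext; bs = ST_D; }
        if (I[u] - ext > best) { best = I[u] - ext; bs = ST_I; }
        if (best > NEG_INF) { I[here] = best; pI[here] = i; sI[here] = bs; }
      }
    }
  }

  // global end: best over end nodes (no successors) at j = m
  double best = NEG_INF; int bi = -1; signed char bstate = -1;
  for (int t = 0; t < n; ++t) {
    int v = order[t];
    if (!g.succs[v].empty()) continue;
    int i = t + 1;
    size_t e = idx(i, m);
    const double cand[3] = {M[e], D[e], I[e]};
    for (int s = 0; s < 3; ++s) {
      if (cand[s] > best) { best = cand[s]; bi = i; bstate = (signed char)s; }
    }
  }
  if (bi < 0) stop("POA alignment failed (empty graph?)");

  AlignResult res;
  res.score = best;
  int i = bi, j = m;
  signed char st = bstate;
  while (!(i == 0 && j == 0)) {
    size_t here = idx(i, j);
    int node = (i == 0) ? -1 : order[i - 1];
    if (st == ST_M) {
      if (i == 0) break;  // reached virtual start cell
      res.op_state.push_back(ST_M);
      res.op_node.push_back(node);
      res.op_qpos.push_back(j - 1);
      signed char ps = sM[here]; int pi = pM[here];
      i = pi; j = j - 1; st = ps;
    } else if (st == ST_D) {
      res.op_state.push_back(ST_D);
      res.op_node.push_back(node);
      res.op_qpos.push_back(-1);
      signed char ps = sD[here]; int pi = pD[here];
      i = pi; st = ps;
    } else {
      res.op_state.push_back(ST_I);
      res.op_node.push_back(-1);
      res.op_qpos.push_back(j - 1);
      signed char ps = sI[here]; int pi = pI[here];
      i = pi; j = j - 1; st = ps;
    }
  }
  std::reverse(res.op_state.begin(), res.op_state.end());
  std::reverse(res.op_node.begin(), res.op_node.end());
  std::reverse(res.op_qpos.begin(), res.op_qpos.end());
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".poa_msa_cpp")]]
List poa_msa_cpp(CharacterVector sequences, double match, double mismatch,
                 double gap_open, double gap_ext) {
  int nseq = sequences.size();
  if (nseq < 1) stop("need at least one sequence");
  std::vector<std::string> seqs(nseq);
  for (int i = 0; i < nseq; ++i) {
    seqs[i] = as<std::string>(sequences[i]);
    if (seqs[i].empty()) stop("empty sequence in POA input");
  }

  PoaGraph g;
  std::vector<std::vector<int> > row_paths(nseq);
  NumericVector scores(nseq, NA_REAL);

  // seed the graph with the first sequence as a chain
  {
    int prev = -1;
    for (size_t p = 0; p < seqs[0].size(); ++p) {
      int v = g.add_node(seqs[0][p], -1);
      if (prev >= 0) g.add_edge(prev, v);
      row_paths[0].push_back(v);
      prev = v;
    }
  }

  for (int s = 1; s < nseq; ++s) {
    AlignResult ar = align_to_graph(g, seqs[s], match, mismatch, gap_open,
                                    gap_ext);
    scores[s] = ar.score;
    std::vector<int> path;
    for (size_t o = 0; o < ar.op_state.size(); ++o) {
      int st = ar.op_state[o];
      if (st == ST_D) continue;  // graph node skipped by this row
      char qb = seqs[s][(size_t)ar.op_qpos[o]];
      int node;
      if (st == ST_M) {
        int v = ar.op_node[o];
        if (g.base[v] == qb) {
          node = v;
        } else {
          node = -1;
          const std::vector<int> &rn = g.ring_nodes[g.ring[v]];
          for (size_t r = 0; r < rn.size(); ++r) {
            if (g.base[rn[r]] == qb) { node = rn[r]; break; }
          }
          if (node < 0) node = g.add_node(qb, g.ring[v]);
        }
      } else {  // ST_I: new node, new ring
        node = g.add_node(qb, -1);
      }
      if (!path.empty()) g.add_edge(path.back(), node);
      path.push_back(node);
    }
    row_paths[s] = path;
  }

  // rings -> MSA columns: toposort the ring DAG (smallest ring id first)
  int nring = (int)g.ring_nodes.size();
  std::vector<std::vector<int> > ring_succ(nring);
  std::vector<int> ring_indeg(nring, 0);
  {
    std::vector<std::vector<bool> > seen(nring);
    for (int r = 0; r < nring; ++r) seen[r].assign(nring, false);
    for (size_t v = 0; v < g.base.size(); ++v) {
      for (size_t e = 0; e < g.succs[v].size(); ++e) {
        int ru = g.ring[v], rv = g.ring[g.succs[v][e]];
        if (ru != rv && !seen[ru][rv]) {
          seen[ru][rv] = true;
          ring_succ[ru].push_back(rv);
          ring_indeg[rv]++;
        }
      }
    }
  }
  std::priority_queue<int, std::vector<int>, std::greater<int> > q;
  for (int r = 0; r < nring; ++r) if (ring_indeg[r] == 0) q.push(r);
  std::vector<int> ring_col(nring, -1);
  int col = 0;
  while (!q.empty()) {
    int r = q.top(); q.pop();
    ring_col[r] = col++;
    for (size_t e = 0; e < ring_succ[r].size(); ++e) {
      if (--ring_indeg[ring_succ[r][e]] == 0) q.push(ring_succ[r][e]);
    }
  }
  if (col != nring) stop("POA ring graph is not acyclic");

  // spell rows over columns
  CharacterVector rows(nseq);
  for (int s = 0; s < nseq; ++s) {
    std::string out(nring, '-');
    for (size_t p = 0; p < row_paths[s].size(); ++p) {
      int v = row_paths[s][p];
      int c = ring_col[g.ring[v]];
      if (out[(size_t)c] != '-') stop("row revisits an MSA column");
      out[(size_t)c] = g.base[v];
    }
    rows[s] = out;
  }

  int nnode = (int)g.base.size();
  CharacterVector node_base(nnode);
  IntegerVector node_col(nnode);
  for (int v = 0; v < nnode; ++v) {
    node_base[v] = std::string(1, g.base[v]);
    node_col[v] = ring_col[g.ring[v]] + 1;  // 1-based for R
  }
  int nedge = 0;
  for (int v = 0; v < nnode; ++v) nedge += (int)g.succs[v].size();
  IntegerMatrix edges(nedge, 2);
  int e = 0;
  for (int v = 0; v < nnode; ++v) {
    for (size_t w = 0; w < g.succs[v].size(); ++w) {
      edges(e, 0) = v + 1;
      edges(e, 1) = g.succs[v][w] + 1;
      ++e;
    }
  }
  List rp(nseq);
  for (int s = 0; s < nseq; ++s) {
    IntegerVector p(row_paths[s].size());
    for (size_t i = 0; i < row_paths[s].size(); ++i) p[i] = row_paths[s][i] + 1;
    rp[s] = p;
  }
  return List::create(_["rows"] = rows, _["scores"] = scores,
                      _["node_base"] = node_base, _["node_col"] = node_col,
                      _["edges"] = edges, _["row_paths"] = rp);
}
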