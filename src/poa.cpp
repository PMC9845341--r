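#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Partial order alignment consensus. Reads are aligned one after another to a
// growing DAG (banded, affine gaps); matched bases merge into existing nodes,
// mismatches and insertions create parallel/new nodes. The consensus is the
// heaviest path through the graph by node support. On equal-length gap-free
// inputs this reduces to column-wise majority voting.

namespace {

struct Graph {
  std::vector<char> base;
  std::vector<int> weight;
  std::vector<std::vector<std::pair<int, int> > > out;  // (to, edge weight)
  int n() const { return (int)base.size(); }
  int add_node(char b) {
    base.push_back(b); weight.push_back(1);
    out.push_back(std::vector<std::pair<int, int> >());
    return (int)base.size() - 1;
  }
  void add_edge(int u, int v) {
    for (size_t t = 0; t < out[u].size(); ++t)
      if (out[u][t].first == v) { out[u][t].second++; return; }
    out[u].push_back(std::make_pair(v, 1));
  }
};

// topological order (graph is built acyclic) + expected-position rank.
// The rank is the edge-weight-weighted mean of predecessor ranks + 1, so
// low-support insertion detours do not inflate the coordinate frame the
// alignment band is anchored to.
void topo_rank(const Graph& g, std::vector<int>& order, std::vector<int>& rank,
               std::vector<std::vector<int> >& preds) {
  int n = g.n();
  std::vector<int> indeg(n, 0);
  preds.assign(n, std::vector<int>());
  for (int u = 0; u < n; ++u)
    for (size_t t = 0; t < g.out[u].size(); ++t) {
      indeg[g.out[u][t].first]++;
      preds[g.out[u][t].first].push_back(u);
    }
  order.clear(); order.reserve(n);
  std::vector<int> q;
  for (int v = 0; v < n; ++v) if (indeg[v] == 0) q.push_back(v);
  std::vector<double> frank(n, 0.0), wsum(n, 0.0);
  rank.assign(n, 0);
  while (!q.empty()) {
    int v = q.back(); q.pop_back();
    order.push_back(v);
    if (wsum[v] > 0) frank[v] /= wsum[v];
    rank[v] = (int)(frank[v] + 0.5);
    for (size_t t = 0; t < g.out[v].size(); ++t) {
      int w = g.out[v][t].first;
      double ew = (double)g.out[v][t].second;
      frank[w] += ew * (frank[v] + 1.0);
      wsum[w] += ew;
      if (--indeg[w] == 0) q.push_back(w);
    }
  }
}

const int NEG16 = -30000;

}  // namespace

// [[Rcpp::export]]
List cpp_poa_consensus(CharacterVector seqs, int match = 2, int mis = -4,
                       int gap_open = -4, int gap_ext = -2, int band = 250) {
  int nreads = seqs.size();
  if (nreads < 1) stop("no sequences");
  Graph g;
  {
    std::string s0 = as<std::string>(seqs[0]);
    if (s0.empty()) stop("empty sequence");
    int prev = g.add_node(s0[0]);
    for (size_t i = 1; i < s0.size(); ++i) {
      int v = g.add_node(s0[i]);
      g.add_edge(prev, v);
      prev = v;
    }
  }
  std::vector<int> order, rank;
  std::vector<std::vector<int> > preds;
  for (int t = 1; t < nreads; ++t) {
    std::string s = as<std::string>(seqs[t]);
    int L = (int)s.size();
    if (L == 0) continue;
    topo_rank(g, order, rank, preds);
    int n = g.n();
    int W = 2 * band + 1;
    // banded DP: for node v, read positions i in [rank[v]-band, rank[v]+band]
    // states: 0=M (node consumed w/ base), 1=X (node consumed, gap in read),
    //         2=Y (base consumed, gap in graph)
    std::vector<short> M((size_t)n * W, NEG16), X((size_t)n * W, NEG16),
        Y((size_t)n * W, NEG16);
    // backpointers: pred slot (0..preds-1, 0xFE=virtual start) + state bits
    std::vector<unsigned char> bpM((size_t)n * W, 0xFF),
        bpX((size_t)n * W, 0xFF), bpY((size_t)n * W, 0xFF);
    std::vector<unsigned char> bsM((size_t)n * W, 0), bsX((size_t)n * W, 0),
        bsY((size_t)n * W, 0);
    // virtual start: score of leaving read prefix of length i unaligned
    std::vector<int> start(L + 1, 0);
    for (int i = 1; i <= L; ++i)
      start[i] = gap_open + (i - 1) * gap_ext;
    int best = NEG16, best_v = -1, best_state = 0, best_i = -1;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int v = order[oi];
      int lo = std::max(0, rank[v] - band), hi = std::min(L, rank[v] + band);
      size_t baseidx = (size_t)v * W;
      const std::vector<int>& pv = preds[v];
      for (int i = lo; i <= hi; ++i) {
        int slot = i - (rank[v] - band);
        // M: node v aligned to read base i (1-based i; requires i >= 1)
        if (i >= 1) {
          int sc = (g.base[v] == s[i - 1]) ? match : mis;
          int bm = start[i - 1] + sc;
          unsigned char bp = 0xFE, bs = 0;
          for (size_t pt = 0; pt < pv.size(); ++pt) {
            int u = pv[pt];
            int uslot = (i - 1) - (rank[u] - band);
            if (uslot < 0 || uslot >= W) continue;
            size_t ui = (size_t)u * W + uslot;
            if (M[ui] + sc > bm) { bm = M[ui] + sc; bp = (unsigned char)pt; bs = 0; }
            if (X[ui] + sc > bm) { bm = X[ui] + sc; bp = (unsigned char)pt; bs = 1; }
            if (Y[ui] + sc > bm) { bm = Y[ui] + sc; bp = (unsigned char)pt; bs = 2; }
          }
          if (bm > NEG16) {
            M[baseidx + slot] = (short)std::max(bm, NEG16 + 1);
            bpM[baseidx + slot] = bp; bsM[baseidx + slot] = bs;
          }
        }
        // X: node v consumed against read gap
        {
          int bm = NEG16; unsigned char bp = 0xFF, bs = 1;
          for (size_t pt = 0; pt < pv.size(); ++pt) {
            int u = pv[pt];
            int uslot = i - (rank[u] - band);
            if (uslot < 0 || uslot >= W) continue;
            size_t ui = (size_t)u * W + uslot;
            if (M[ui] + gap_open > bm) { bm = M[ui] + gap_open; bp = (unsigned char)pt; bs = 0; }
            if (X[ui] + gap_ext > bm) { bm = X[ui] + gap_ext; bp = (unsigned char)pt; bs = 1; }
            if (Y[ui] + gap_open > bm) { bm = Y[ui] + gap_open; bp = (unsigned char)pt; bs = 2; }
          }
          if (bm > NEG16) {
            X[baseidx + slot] = (short)std::max(bm, NEG16 + 1);
            bpX[baseidx + slot] = bp; bsX[baseidx + slot] = bs;
          }
        }
        // Y: read base i consumed against graph gap at node v
        if (i >= 1 && i - 1 >= lo) {
          int pslot = (i - 1) - (rank[v] - band);
          if (pslot >= 0) {
            size_t pi = baseidx + pslot;
            int bm = NEG16; unsigned char bs = 0;
            if (M[pi] + gap_open > bm) { bm = M[pi] + gap_open; bs = 0; }
            if (Y[pi] + gap_ext > bm) { bm = Y[pi] + gap_ext; bs = 2; }
            if (bm > NEG16) {
              Y[baseidx + slot] = (short)std::max(bm, NEG16 + 1);
              bpY[baseidx + slot] = 0xFD;  // same node
              bsY[baseidx + slot] = bs;
            }
          }
        }
      }
      // track best read-complete cell (graph suffix free)
      int islot = L - (rank[v] - band);
      if (islot >= 0 && islot < W) {
        size_t ci = baseidx + islot;
        if (M[ci] > best) { best = M[ci]; best_v = v; best_state = 0; best_i = L; }
        if (Y[ci] > best) { best = Y[ci]; best_v = v; best_state = 2; best_i = L; }
      }
    }
    if (best_v < 0) continue;  // read could not be placed in band; skip
    // traceback: collect (read_pos, node or -1) for consumed read bases
    std::vector<int> map_node(L, -2);  // -1 = insertion (new node), else node
    int v = best_v, st = best_state, i = best_i;
    while (true) {
      int slot = i - (rank[v] - band);
      size_t ci = (size_t)v * W + slot;
      unsigned char bp, bs;
      if (st == 0) { bp = bpM[ci]; bs = bsM[ci]; }
      else if (st == 1) { bp = bpX[ci]; bs = bsX[ci]; }
      else { bp = bpY[ci]; bs = bsY[ci]; }
      if (st == 0) { map_node[i - 1] = v; --i; }
      else if (st == 2) { map_node[i - 1] = -1; --i; }
      if (bp == 0xFF) break;          // start of X chain from nothing
      if (bp == 0xFE) break;          // virtual start (read prefix insertion)
      if (bp == 0xFD) { st = bs; continue; }  // Y: stay on node
      v = preds[v][bp]; st = bs;
      if (i == 0 && st != 1) break;
    }
    // integrate read into graph
    int prev_node = -1;
    for (int p = 0; p < L; ++p) {
      int nd = map_node[p];
      int cur;
      if (nd >= 0 && g.base[nd] == s[p]) {
        g.weight[nd]++; cur = nd;
      } else {
        cur = g.add_node(s[p]);  // mismatch or insertion: parallel/new node
      }
      if (prev_node >= 0 && prev_node != cur) g.add_edge(prev_node, cur);
      prev_node = cur;
    }
  }
  // consensus: heaviest path by accumulated edge weight (ties broken by
  // node weight), as in classic POA consensus; this avoids detours through
  // low-support insertion nodes that a node-weight sum would reward
  topo_rank(g, order, rank, preds);
  int n = g.n();
  // edge weight lookup aligned with preds
  std::vector<std::vector<int> > predw(n);
  for (int v = 0; v < n; ++v) predw[v].assign(preds[v].size(), 0);
  for (int u = 0; u < n; ++u)
    for (size_t t = 0; t < g.out[u].size(); ++t) {
      int w = g.out[u][t].first;
      for (size_t p = 0; p < preds[w].size(); ++p)
        if (preds[w][p] == u) { predw[w][p] = g.out[u][t].second; break; }
    }
  // per-step penalty: a path is only extended over edges whose weight is
  // worth taking, so low-support insertion detours (which would otherwise
  // inflate a summed-weight path) are skipped
  int maxw = 1;
  for (int v = 0; v < n; ++v)
    for (size_t t = 0; t < predw[v].size(); ++t)
      if (predw[v][t] > maxw) maxw = predw[v][t];
  double lambda = 0.25 * maxw;
  std::vector<double> dp(n, 0.0);
  std::vector<int> from(n, -1);
  double best = -1; int best_v = 0;
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int v = order[oi];
    double b = 0; int f = -1;
    for (size_t t = 0; t < preds[v].size(); ++t) {
      int u = preds[v][t];
      double cand = dp[u] + (predw[v][t] - lambda) +
                    1e-6 * std::min(g.weight[u], g.weight[v]);
      if (cand > b) { b = cand; f = u; }
    }
    dp[v] = b;
    from[v] = f;
    double sc = dp[v] + 1e-6 * g.weight[v];
    if (sc > best) { best = sc; best_v = v; }
  }
  std::string cons;
  for (int v = best_v; v >= 0; v = from[v]) cons.push_back(g.base[v]);
  std::reverse(cons.begin(), cons.end());
  return List::create(_["seq"] = cons, _["n_reads"] = nreads,
                      _["n_nodes"] = n);
}
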