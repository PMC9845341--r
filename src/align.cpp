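#include <Rcpp.h>
#include <cstring>
#include <unordered_map>
using namespace Rcpp;

// Pairwise alignment kernels. Scores are small integers; all DPs use rolling
// rows so memory stays O(reference length).

static inline int subst(char a, char b, int match, int mis) {
  return (a == b && a != 'N') ? match : mis;
}

// Smith-Waterman (linear gap) forward pass keeping, for every query prefix
// length i, the best local-alignment score ending at query position i together
// with the reference column where it ends. Ties prefer the smaller column.
static void sw_rowmax(const std::string& q, const std::string& r, int match,
                      int mis, int gap, std::vector<int>& best,
                      std::vector<int>& bestj) {
  int m = q.size(), n = r.size();
  best.assign(m + 1, 0); bestj.assign(m + 1, 0);
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0;
    int rowbest = 0, rowj = 0;
    const char qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      int s = prev[j - 1] + subst(qi, r[j - 1], match, mis);
      int s2 = prev[j] + gap;
      if (s2 > s) s = s2;
      int s3 = cur[j - 1] + gap;
      if (s3 > s) s = s3;
      if (s < 0) s = 0;
      cur[j] = s;
      if (s > rowbest) { rowbest = s; rowj = j; }
    }
    best[i] = rowbest; bestj[i] = rowj;
    std::swap(prev, cur);
  }
}

// Join alignment: best split of the query into a prefix aligned locally to the
// reference and a suffix aligned locally downstream (or upstream: the
// reference-side jump is unconstrained, so a negative jump models a tandem
// duplication junction and a positive jump a deletion).
// Returns 0-based coordinates: jF = reference position just after the last
// prefix column, jB = reference position of the first suffix column.
// [[Rcpp::export]]
List cpp_align_join(std::string q, std::string r, int match = 2, int mis = -4,
                    int gap = -4) {
  int m = q.size();
  std::vector<int> fb, fj, bb, bj;
  sw_rowmax(q, r, match, mis, gap, fb, fj);
  std::string qr(q.rbegin(), q.rend()), rr(r.rbegin(), r.rend());
  sw_rowmax(qr, rr, match, mis, gap, bb, bj);
  // bb[k]: best local score ending at reversed-query position k
  // == starting at query position m-k (0-based) in forward space.
  int best = -1, best_i = 0, best_jF = 0, best_jB = 0;
  int n = r.size();
  for (int i = 1; i < m; ++i) {
    int k = m - i;  // suffix q[i..m) has reversed prefix length k
    int sc = fb[i] + bb[k];
    if (sc > best) {
      best = sc; best_i = i;
      best_jF = fj[i];                 // ref cols used: 1..jF -> end = jF
      best_jB = n - bj[k];             // 0-based start col of suffix part
    }
  }
  int full = 0;
  for (int i = 0; i <= m; ++i) if (fb[i] > full) full = fb[i];
  return List::create(_["join_score"] = best, _["i"] = best_i,
                      _["jF"] = best_jF, _["jB"] = best_jB,
                      _["local_best"] = full);
}

// Local alignment with one long query-side gap state (for insertion
// discovery): M is plain Smith-Waterman; J carries an open long gap that
// consumes query bases for free after a fixed opening penalty. Origins of the
// gap (query open/close positions and the reference column) are propagated so
// the inserted interval can be reported without a traceback matrix.
// [[Rcpp::export]]
List cpp_align_ins(std::string q, std::string r, int match = 2, int mis = -4,
                   int gap = -4, int big_open = -24) {
  int m = q.size(), n = r.size();
  const int NEG = -1000000000;
  std::vector<int> Mp(n + 1, 0), Mc(n + 1, 0);
  std::vector<int> Jp(n + 1, NEG), Jc(n + 1, NEG);
  // origin fields propagated with M (after a gap) and J (while open)
  std::vector<int> Mi0p(n + 1, -1), Mi1p(n + 1, -1), Mjp(n + 1, -1);
  std::vector<int> Mi0c(n + 1, -1), Mi1c(n + 1, -1), Mjc(n + 1, -1);
  std::vector<int> Ji0p(n + 1, -1), Ji0c(n + 1, -1), Jjp(n + 1, -1),
      Jjc(n + 1, -1);
  int best = 0, b_i0 = -1, b_i1 = -1, b_j = -1;
  int plain_best = 0;
  for (int i = 1; i <= m; ++i) {
    Mc[0] = 0; Jc[0] = NEG;
    Mi0c[0] = Mi1c[0] = Mjc[0] = -1; Ji0c[0] = Jjc[0] = -1;
    const char qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      // J state: open from M (no gap yet), or extend
      int open = (Mjp[j] < 0) ? Mp[j] + big_open : NEG;
      int ext = Jp[j];
      if (open >= ext) {
        Jc[j] = open; Ji0c[j] = i - 1; Jjc[j] = j;
      } else {
        Jc[j] = ext; Ji0c[j] = Ji0p[j]; Jjc[j] = Jjp[j];
      }
      // M state
      int s = subst(qi, r[j - 1], match, mis);
      int diag = Mp[j - 1] + s;
      int up = Mp[j] + gap;
      int left = Mc[j - 1] + gap;
      int fromJ = Jp[j - 1] + s;
      int val = diag; int src = 0;
      if (up > val) { val = up; src = 1; }
      if (left > val) { val = left; src = 2; }
      if (fromJ > val) { val = fromJ; src = 3; }
      if (val < 0) { val = 0; src = 4; }
      Mc[j] = val;
      switch (src) {
      case 0: Mi0c[j] = Mi0p[j - 1]; Mi1c[j] = Mi1p[j - 1]; Mjc[j] = Mjp[j - 1]; break;
      case 1: Mi0c[j] = Mi0p[j]; Mi1c[j] = Mi1p[j]; Mjc[j] = Mjp[j]; break;
      case 2: Mi0c[j] = Mi0c[j - 1]; Mi1c[j] = Mi1c[j - 1]; Mjc[j] = Mjc[j - 1]; break;
      case 3: Mi0c[j] = Ji0p[j - 1]; Mi1c[j] = i - 1; Mjc[j] = Jjp[j - 1]; break;
      default: Mi0c[j] = -1; Mi1c[j] = -1; Mjc[j] = -1; break;
      }
      if (Mc[j] > best && Mjc[j] >= 0) {
        best = Mc[j]; b_i0 = Mi0c[j]; b_i1 = Mi1c[j]; b_j = Mjc[j];
      }
      if (Mc[j] > plain_best && Mjc[j] < 0) plain_best = Mc[j];
    }
    std::swap(Mp, Mc); std::swap(Jp, Jc);
    std::swap(Mi0p, Mi0c); std::swap(Mi1p, Mi1c); std::swap(Mjp, Mjc);
    std::swap(Ji0p, Ji0c); std::swap(Jjp, Jjc);
  }
  // b_i0: 0-based query pos where gap opened (gap covers q[b_i0, b_i1))
  return List::create(_["score"] = best, _["q_gap_start"] = b_i0,
                      _["q_gap_end"] = b_i1, _["ref_pos"] = b_j,
                      _["plain_best"] = plain_best);
}

// Full local alignment with affine gaps and traceback; intended for
// moderate-size inputs (identity checks, duplication rescue, overlap
// verification). Returns match/aligned counts along the optimal path.
// [[Rcpp::export]]
List cpp_align_local(std::string q, std::string r, int match = 2, int mis = -4,
                     int gap_open = -4, int gap_ext = -2) {
  int m = q.size(), n = r.size();
  if ((double)m * n > 4.5e8)
    stop("cpp_align_local: input too large (%d x %d)", m, n);
  const int NEG = -1000000000;
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Ep(n + 1, NEG), Ec(n + 1, NEG),
      Fc(n + 1, NEG);
  // traceback: 2 bits per state per cell; store byte
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hc[0] = 0; Fc[0] = NEG;
    const char qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      int e = std::max(Hp[j] + gap_open, Ep[j] + gap_ext);   // gap in ref (up)
      int f = std::max(Hc[j - 1] + gap_open, Fc[j - 1] + gap_ext);
      int d = Hp[j - 1] + subst(qi, r[j - 1], match, mis);
      int h = d; unsigned char t = 1;         // 1=diag 2=up 3=left 0=stop
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      Ec[j] = e; Fc[j] = f; Hc[j] = h;
      tb[(size_t)i * (n + 1) + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc); std::swap(Ep, Ec);
  }
  // traceback
  int i = bi, j = bj, n_match = 0, n_cols = 0, q_aln = 0;
  int qe = bi, re = bj;
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (n + 1) + j];
    if (t == 0) break;
    if (t == 1) {
      ++n_cols; ++q_aln;
      if (q[i - 1] == r[j - 1]) ++n_match;
      --i; --j;
    } else if (t == 2) { ++n_cols; ++q_aln; --i; }
    else { ++n_cols; --j; }
  }
  return List::create(_["score"] = best, _["q_start"] = i, _["q_end"] = qe,
                      _["r_start"] = j, _["r_end"] = re,
                      _["n_match"] = n_match, _["n_cols"] = n_cols,
                      _["q_aligned"] = q_aln);
}

// Estimate the diagonal offset (pos_in_a - pos_in_b) between two sequences by
// voting over shared k-mers (2-bit encoded, k <= 15), binned to 32 bp.
// Returns c(best_diag, votes, total_kmer_hits).
// [[Rcpp::export]]
IntegerVector cpp_seed_offset(std::string a, std::string b, int k = 15,
                              int max_occ = 8) {
  if (k < 8 || k > 15) stop("k must be in [8,15]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, std::vector<int> > index;
  auto code2 = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
                 case 'T': return 3; default: return -1; }
  };
  uint64_t key = 0; int run = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int c = code2(a[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::vector<int>& v = index[key];
      if ((int)v.size() < max_occ) v.push_back((int)i - k + 1);
    }
  }
  std::unordered_map<int, int> votes;
  key = 0; run = 0; int total = 0;
  for (size_t i = 0; i < b.size(); ++i) {
    int c = code2(b[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto it = index.find(key);
      if (it != index.end()) {
        int posb = (int)i - k + 1;
        for (size_t t = 0; t < it->second.size(); ++t) {
          int diag = it->second[t] - posb;
          votes[diag / 32]++;
          ++total;
        }
      }
    }
  }
  int best_bin = 0, best_votes = 0;
  for (auto& kv : votes) {
    if (kv.second > best_votes) { best_votes = kv.second; best_bin = kv.first; }
  }
  return IntegerVector::create(best_bin * 32 + 16, best_votes, total);
}
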