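#include <Rcpp.h>
#include <map>
#include <cstring>
using namespace Rcpp;

// Banded semiglobal alignment against a fixed diagonal offset, plus the
// pileup-vote polishing used by the clip-anchored local assembler.

namespace {

const int NEG = -1000000000;

struct BandAln {
  int score, n_match, n_cols;
  int a_start, a_end, b_start, b_end;           // 0-based half-open
  std::vector<unsigned char> ops;               // in order: 1=diag 2=up(a) 3=left(b)
  std::vector<int> opj;                         // b column (1-based) per op
  std::vector<int> opi;                         // a row (1-based) per op
  bool ok;
};

// Align a (rows) to b (cols) inside band |j - i - diag| <= band.
// Free leading/trailing gaps on both sequences (semiglobal).
void band_align(const std::string& a, const std::string& b, int diag, int band,
                int match, int mis, int gap, BandAln& out, bool want_path) {
  int m = a.size(), n = b.size(), W = 2 * band + 1;
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<unsigned char>* tb = NULL;
  std::vector<unsigned char> tbv;
  if (want_path) {
    tbv.assign((size_t)(m + 1) * W, 0);
    tb = &tbv;
  }
  // row 0: j = diag - band + s
  for (int s = 0; s < W; ++s) {
    int j = diag - band + s;
    if (j >= 0 && j <= n) prev[s] = 0;  // free start anywhere on b
  }
  int best = NEG, bi = 0, bs = 0;
  // allow starting with unaligned a prefix: row i col j where j in band and
  // alignment starts fresh -> treat as score 0 start at (i-1, j) diag step.
  for (int i = 1; i <= m; ++i) {
    const char ai = a[i - 1];
    for (int s = 0; s < W; ++s) cur[s] = NEG;
    int jlo = std::max(0, i + diag - band), jhi = std::min(n, i + diag + band);
    for (int j = jlo; j <= jhi; ++j) {
      int s = j - (i + diag - band);
      int v = NEG; unsigned char t = 0;
      if (j >= 1) {
        int ps = s;  // (i-1, j-1): slot (j-1)-((i-1)+diag-band) = s
        if (ps >= 0 && ps < W && prev[ps] > NEG) {
          int d = prev[ps] + ((ai == b[j - 1] && ai != 'N') ? match : mis);
          if (d > v) { v = d; t = 1; }
        }
      }
      {
        int ps = s + 1;  // (i-1, j): slot j-((i-1)+diag-band) = s+1
        if (ps >= 0 && ps < W && prev[ps] > NEG) {
          int u = prev[ps] + gap;
          if (u > v) { v = u; t = 2; }
        }
      }
      if (s - 1 >= 0 && cur[s - 1] > NEG) {
        int l = cur[s - 1] + gap;
        if (l > v) { v = l; t = 3; }
      }
      if (v <= NEG) continue;
      cur[s] = v;
      if (want_path) (*tb)[(size_t)i * W + s] = t;
      if ((i == m || j == n) && v > best) { best = v; bi = i; bs = s; }
    }
    std::swap(prev, cur);
    if (i == m) {
      // prev now holds row m
      for (int s = 0; s < W; ++s) {
        int j = m + diag - band + s;
        if (j >= 0 && j <= n && prev[s] > best) { best = prev[s]; bi = m; bs = s; }
      }
    }
  }
  out.ok = best > NEG;
  out.score = best;
  out.n_match = 0; out.n_cols = 0;
  out.ops.clear(); out.opj.clear(); out.opi.clear();
  if (!out.ok) return;
  out.a_end = bi; out.b_end = bi + diag - band + bs;
  if (!want_path) { out.a_start = 0; out.b_start = 0; return; }
  // traceback
  int i = bi, s = bs;
  std::vector<unsigned char> rops; std::vector<int> rj, ri;
  while (i > 0) {
    int j = i + diag - band + s;
    unsigned char t = (*tb)[(size_t)i * W + s];
    if (t == 0) break;
    rops.push_back(t); rj.push_back(j); ri.push_back(i);
    if (t == 1) {
      if (a[i - 1] == b[j - 1]) out.n_match++;
      out.n_cols++;
      --i;  // slot of j-1 in row i-1 is same s
    } else if (t == 2) {
      out.n_cols++;
      --i; s = s + 1;
    } else {
      out.n_cols++;
      s = s - 1;
    }
  }
  out.a_start = i;
  out.b_start = i + diag - band + s;
  std::reverse(rops.begin(), rops.end());
  std::reverse(rj.begin(), rj.end());
  std::reverse(ri.begin(), ri.end());
  out.ops = rops; out.opj = rj; out.opi = ri;
}

}  // namespace

// [[Rcpp::export]]
List cpp_align_banded_ident(std::string a, std::string b, int diag, int band,
                            int match = 2, int mis = -4, int gap = -4) {
  BandAln res;
  band_align(a, b, diag, band, match, mis, gap, res, true);
  if (!res.ok)
    return List::create(_["score"] = NA_INTEGER);
  return List::create(_["score"] = res.score, _["n_match"] = res.n_match,
                      _["n_cols"] = res.n_cols, _["a_start"] = res.a_start,
                      _["a_end"] = res.a_end, _["b_start"] = res.b_start,
                      _["b_end"] = res.b_end);
}

// Polish a backbone sequence by banded alignment of anchored reads followed
// by per-column majority voting (bases, deletions, and inserted strings).
// offset[t]: expected backbone position of read t's first base.
// Reads whose alignment identity is below min_ident are left out and flagged.
// [[Rcpp::export]]
List cpp_pileup_polish(std::string backbone, CharacterVector reads,
                       IntegerVector offset, int band = 150,
                       double min_ident = 0.55, int match = 2, int mis = -4,
                       int gap = -4, double min_cols_frac = 0.5) {
  int nb = backbone.size();
  int nr = reads.size();
  std::vector<std::array<int, 5> > cnt(nb);  // A C G T del
  for (int j = 0; j < nb; ++j) cnt[j].fill(0);
  std::vector<std::map<std::string, int> > ins_at(nb + 1);
  auto bidx = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
                 case 'T': return 3; default: return -1; }
  };
  // backbone's own vote
  for (int j = 0; j < nb; ++j) {
    int k = bidx(backbone[j]);
    if (k >= 0) cnt[j][k]++;
  }
  LogicalVector used(nr);
  NumericVector idents(nr);
  BandAln res;
  for (int t = 0; t < nr; ++t) {
    std::string s = as<std::string>(reads[t]);
    band_align(s, backbone, offset[t], band, match, mis, gap, res, true);
    double ident = (res.ok && res.n_cols > 0)
                       ? (double)res.n_match / res.n_cols : 0.0;
    idents[t] = ident;
    // a read must align over a substantial fraction of its length, or a
    // short lucky suffix/prefix overlap of an unrelated read would pass
    int need_cols = (int)(min_cols_frac *
                          std::min(s.size(), (size_t)nb));
    if (!res.ok || ident < min_ident || res.n_cols < need_cols) {
      used[t] = false; continue;
    }
    used[t] = true;
    std::string pending;  // inserted bases awaiting attachment
    for (size_t p = 0; p < res.ops.size(); ++p) {
      unsigned char op = res.ops[p];
      int j = res.opj[p], i = res.opi[p];
      if (op == 1) {
        if (!pending.empty()) {
          ins_at[j - 1][pending]++;
          pending.clear();
        }
        int k = bidx(s[i - 1]);
        if (k >= 0) cnt[j - 1][k]++;
      } else if (op == 2) {
        pending.push_back(s[i - 1]);
      } else {
        if (!pending.empty()) {
          ins_at[j - 1][pending]++;
          pending.clear();
        }
        cnt[j - 1][4]++;
      }
    }
    if (!pending.empty()) ins_at[res.b_end][pending]++;
  }
  // consensus build
  std::string out;
  out.reserve(nb + 64);
  const char* B = "ACGT";
  for (int j = 0; j <= nb; ++j) {
    int covm = 0;
    if (j < nb) for (int k = 0; k < 5; ++k) covm += cnt[j][k];
    int covl = 0;
    if (j > 0) for (int k = 0; k < 5; ++k) covl += cnt[j - 1][k];
    int cov = std::max(covm, covl);
    if (!ins_at[j].empty()) {
      int bc = 0; const std::string* bs = NULL;
      for (std::map<std::string, int>::const_iterator it = ins_at[j].begin();
           it != ins_at[j].end(); ++it)
        if (it->second > bc) { bc = it->second; bs = &it->first; }
      if (bs && 2 * bc > cov) out += *bs;
    }
    if (j == nb) break;
    int bk = -1, bc = -1;
    for (int k = 0; k < 5; ++k)
      if (cnt[j][k] > bc) { bc = cnt[j][k]; bk = k; }
    // ties favour the backbone base
    int bb = bidx(backbone[j]);
    if (bb >= 0 && cnt[j][bb] == bc) bk = bb;
    if (bk == 4) continue;  // majority deletion
    if (bk < 0) out.push_back(backbone[j]);
    else out.push_back(B[bk]);
  }
  return List::create(_["seq"] = out, _["used"] = used, _["ident"] = idents);
}
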