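#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// CIGAR op codes used throughout: 0=M 1=I 2=D 3=S 4=H 5=N 6='=' 7=X 8=P
static inline int op_code(char c) {
  switch (c) {
  case 'M': return 0; case 'I': return 1; case 'D': return 2;
  case 'S': return 3; case 'H': return 4; case 'N': return 5;
  case '=': return 6; case 'X': return 7; case 'P': return 8;
  default: return -1;
  }
}
static const char OP_CHARS[] = "MIDSHN=XP";

static inline bool consumes_read(int op) {
  return op == 0 || op == 1 || op == 3 || op == 6 || op == 7;
}
static inline bool consumes_ref(int op) {
  return op == 0 || op == 2 || op == 5 || op == 6 || op == 7;
}
static inline bool is_match(int op) { return op == 0 || op == 6 || op == 7; }

static void parse_cigar_str(const std::string& cig, std::vector<int>& ops,
                            std::vector<int>& lens) {
  ops.clear(); lens.clear();
  long n = 0;
  for (size_t i = 0; i < cig.size(); ++i) {
    char c = cig[i];
    if (std::isdigit((unsigned char)c)) {
      n = n * 10 + (c - '0');
    } else {
      int op = op_code(c);
      if (op < 0 || n <= 0) stop("malformed CIGAR: %s", cig.c_str());
      ops.push_back(op); lens.push_back((int)n);
      n = 0;
    }
  }
  if (n != 0) stop("malformed CIGAR (trailing digits): %s", cig.c_str());
}

// [[Rcpp::export]]
List cpp_parse_cigar(std::string cigar) {
  std::vector<int> ops, lens;
  parse_cigar_str(cigar, ops, lens);
  return List::create(_["op"] = wrap(ops), _["len"] = wrap(lens));
}

// [[Rcpp::export]]
std::string cpp_ops_to_cigar(IntegerVector op, IntegerVector len) {
  std::string out;
  char buf[16];
  for (int i = 0; i < op.size(); ++i) {
    if (len[i] <= 0) continue;
    snprintf(buf, sizeof(buf), "%d", (int)len[i]);
    out += buf;
    out += OP_CHARS[op[i]];
  }
  return out;
}

// Per-record CIGAR summaries.
// Columns: ref_len, read_len (incl. S, excl. H), lead_clip, trail_clip (S+H),
// aligned_read (M+I bases), lead_S, trail_S
// [[Rcpp::export]]
IntegerMatrix cpp_cigar_stats(CharacterVector cigars) {
  int n = cigars.size();
  IntegerMatrix out(n, 7);
  colnames(out) = CharacterVector::create("ref_len", "read_len", "lead_clip",
            "trail_clip", "aligned_read", "lead_S", "trail_S");
  std::vector<int> ops, lens;
  for (int r = 0; r < n; ++r) {
    parse_cigar_str(as<std::string>(cigars[r]), ops, lens);
    int ref_len = 0, read_len = 0, aligned = 0;
    int lead = 0, trail = 0, leadS = 0, trailS = 0;
    int m = ops.size();
    int i0 = 0, i1 = m;
    while (i0 < i1 && (ops[i0] == 3 || ops[i0] == 4)) {
      lead += lens[i0];
      if (ops[i0] == 3) leadS += lens[i0];
      ++i0;
    }
    while (i1 > i0 && (ops[i1 - 1] == 3 || ops[i1 - 1] == 4)) {
      --i1;
      trail += lens[i1];
      if (ops[i1] == 3) trailS += lens[i1];
    }
    for (int i = 0; i < m; ++i) {
      if (consumes_ref(ops[i])) ref_len += lens[i];
      if (ops[i] != 4 && consumes_read(ops[i])) read_len += lens[i];
      if (is_match(ops[i]) || ops[i] == 1) aligned += lens[i];
    }
    out(r, 0) = ref_len; out(r, 1) = read_len;
    out(r, 2) = lead; out(r, 3) = trail;
    out(r, 4) = aligned; out(r, 5) = leadS; out(r, 6) = trailS;
  }
  return out;
}

// Intra-alignment raw signal extraction over many records at once.
// Same-type ops >= min_size are merged when the intervening gap (read gap for
// I, reference gap for D) is <= max(merge_fixed, merge_frac * summed size).
// Returns one row per signal: rec (1-based record index), type (1=INS 2=DEL),
// pos (0-based ref), size, read_off (0-based offset in stored read of first
// inserted base; NA for DEL), ins_seq (NA when seqs[rec] is NA or DEL).
// [[Rcpp::export]]
DataFrame cpp_intra_signals(CharacterVector cigars, IntegerVector ref_start,
                            CharacterVector seqs, int min_size,
                            int merge_fixed = 100, double merge_frac = 0.5) {
  std::vector<int> o_rec, o_type, o_pos, o_size, o_off;
  std::vector<std::string> o_seq;
  std::vector<bool> o_has_seq;
  std::vector<int> ops, lens;

  struct Cand { int type, pos, size, read_off, end_ref, end_read; std::string content; };

  for (int r = 0; r < cigars.size(); ++r) {
    parse_cigar_str(as<std::string>(cigars[r]), ops, lens);
    bool has_seq = !CharacterVector::is_na(seqs[r]);
    std::string seq = has_seq ? as<std::string>(seqs[r]) : std::string();
    int rpos = ref_start[r], qpos = 0;
    std::vector<Cand> cands;
    for (size_t i = 0; i < ops.size(); ++i) {
      int op = ops[i], len = lens[i];
      if (op == 1 && len >= min_size) {
        Cand c; c.type = 1; c.pos = rpos; c.size = len; c.read_off = qpos;
        c.end_ref = rpos; c.end_read = qpos + len;
        if (has_seq) c.content = seq.substr(qpos, len);
        cands.push_back(c);
      } else if ((op == 2 || op == 5) && len >= min_size) {
        Cand c; c.type = 2; c.pos = rpos; c.size = len; c.read_off = -1;
        c.end_ref = rpos + len; c.end_read = qpos;
        cands.push_back(c);
      }
      if (op != 4 && consumes_read(op)) qpos += len;
      if (consumes_ref(op)) rpos += len;
    }
    // left-to-right greedy merge of same-type neighbours
    std::vector<Cand> merged;
    for (size_t i = 0; i < cands.size(); ++i) {
      if (!merged.empty() && merged.back().type == cands[i].type) {
        Cand& a = merged.back();
        const Cand& b = cands[i];
        long gap = (b.type == 1) ? (long)b.read_off - a.end_read
                                 : (long)b.pos - a.end_ref;
        double lim = std::max((double)merge_fixed,
                              merge_frac * (a.size + b.size));
        if (gap >= 0 && gap <= lim) {
          a.size += b.size;
          a.end_ref = b.end_ref; a.end_read = b.end_read;
          if (b.type == 1) a.content += b.content;
          continue;
        }
      }
      merged.push_back(cands[i]);
    }
    for (size_t i = 0; i < merged.size(); ++i) {
      const Cand& c = merged[i];
      o_rec.push_back(r + 1); o_type.push_back(c.type);
      o_pos.push_back(c.pos); o_size.push_back(c.size);
      o_off.push_back(c.type == 1 ? c.read_off : NA_INTEGER);
      o_has_seq.push_back(c.type == 1 && has_seq);
      o_seq.push_back(c.type == 1 && has_seq ? c.content : std::string());
    }
  }
  int n = o_rec.size();
  CharacterVector ins_seq(n);
  for (int i = 0; i < n; ++i) {
    if (o_has_seq[i]) ins_seq[i] = o_seq[i]; else ins_seq[i] = NA_STRING;
  }
  return DataFrame::create(_["rec"] = wrap(o_rec), _["type"] = wrap(o_type),
                           _["pos"] = wrap(o_pos), _["size"] = wrap(o_size),
                           _["read_off"] = wrap(o_off), _["ins_seq"] = ins_seq,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) {
    switch (out[i]) {
    case 'A': out[i] = 'T'; break; case 'T': out[i] = 'A'; break;
    case 'C': out[i] = 'G'; break; case 'G': out[i] = 'C'; break;
    case 'a': out[i] = 't'; break; case 't': out[i] = 'a'; break;
    case 'c': out[i] = 'g'; break; case 'g': out[i] = 'c'; break;
    default: break;
    }
  }
  return out;
}

// Read-coordinate interval (stored orientation, counting soft clips) covering
// reference window [ref_lo, ref_hi). Returns c(read_lo, read_hi, spans) where
// spans is 1 when the record's aligned part covers the whole window.
// [[Rcpp::export]]
IntegerVector cpp_read_window(std::string cigar, int ref_start, int ref_lo,
                              int ref_hi) {
  std::vector<int> ops, lens;
  parse_cigar_str(cigar, ops, lens);
  int rpos = ref_start, qpos = 0;
  int aln_ref_start = ref_start, aln_ref_end = ref_start;
  int read_lo = -1, read_hi = -1;
  for (size_t i = 0; i < ops.size(); ++i) {
    int op = ops[i], len = lens[i];
    if (is_match(op)) {
      // overlap of [rpos, rpos+len) with window
      int lo = std::max(rpos, ref_lo), hi = std::min(rpos + len, ref_hi);
      if (lo < hi) {
        int q_lo = qpos + (lo - rpos), q_hi = qpos + (hi - rpos);
        if (read_lo < 0) read_lo = q_lo;
        read_hi = q_hi;
      }
      aln_ref_end = rpos + len;
    } else if (op == 1) {
      if (rpos > ref_lo && rpos < ref_hi && read_lo >= 0) read_hi = qpos + len;
    }
    if (op != 4 && consumes_read(op)) qpos += len;
    if (consumes_ref(op)) rpos += len;
  }
  aln_ref_end = rpos;
  int spans = (aln_ref_start <= ref_lo && aln_ref_end >= ref_hi) ? 1 : 0;
  return IntegerVector::create(read_lo, read_hi, spans);
}

// Read-orientation coordinates of each record's aligned block.
// For '-' strand records the stored orientation is reversed.
// [[Rcpp::export]]
IntegerMatrix cpp_read_span(IntegerVector read_len, IntegerVector lead_clip,
                            IntegerVector trail_clip, LogicalVector fwd) {
  int n = read_len.size();
  IntegerMatrix out(n, 2);
  colnames(out) = CharacterVector::create("read_start", "read_end");
  for (int i = 0; i < n; ++i) {
    if (fwd[i]) {
      out(i, 0) = lead_clip[i];
      out(i, 1) = read_len[i] - trail_clip[i];
    } else {
      out(i, 0) = trail_clip[i];
      out(i, 1) = read_len[i] - lead_clip[i];
    }
  }
  return out;
}
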