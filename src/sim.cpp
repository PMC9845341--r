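#include <Rcpp.h>
using namespace Rcpp;

// Error-edit helpers for the read simulator. Edit positions are 0-based
// coordinates on the clean read; an insertion adds one base *before* the
// given position, a deletion removes the base at the position. Positions are
// assumed distinct across the three edit classes (the R side samples them
// without replacement from a shared pool).

// [[Rcpp::export]]
std::string cpp_apply_edits_seq(std::string seq, IntegerVector sub_pos,
                                CharacterVector sub_base, IntegerVector ins_pos,
                                CharacterVector ins_base,
                                IntegerVector del_pos) {
  int L = seq.size();
  std::vector<char> sub(L, 0), ins(L + 1, 0);
  std::vector<bool> del(L, false);
  for (int k = 0; k < sub_pos.size(); ++k)
    sub[sub_pos[k]] = as<std::string>(sub_base[k])[0];
  for (int k = 0; k < ins_pos.size(); ++k)
    ins[ins_pos[k]] = as<std::string>(ins_base[k])[0];
  for (int k = 0; k < del_pos.size(); ++k) del[del_pos[k]] = true;
  std::string out;
  out.reserve(L + ins_pos.size());
  for (int p = 0; p <= L; ++p) {
    if (ins[p]) out.push_back(ins[p]);
    if (p == L) break;
    if (del[p]) continue;
    out.push_back(sub[p] ? sub[p] : seq[p]);
  }
  return out;
}

// Rewrite a segment's CIGAR-style op list (codes 0=M 1=I 2=D 3=S) expressed on
// clean-read coordinates, injecting 1 bp I/D ops for error insertions and
// deletions that fall inside the segment's read span. read0 is the clean-read
// coordinate where the op list starts. Adjacent same-type ops are merged.
// [[Rcpp::export]]
List cpp_inject_edits_ops(IntegerVector op, IntegerVector len, int read0,
                          IntegerVector ins_pos, IntegerVector del_pos) {
  // collect edits sorted by position
  std::vector<std::pair<int, int> > edits;  // (pos, type 1=ins 2=del)
  for (int k = 0; k < ins_pos.size(); ++k)
    edits.push_back(std::make_pair(ins_pos[k], 1));
  for (int k = 0; k < del_pos.size(); ++k)
    edits.push_back(std::make_pair(del_pos[k], 2));
  std::sort(edits.begin(), edits.end());
  std::vector<int> oo, ol;
  size_t e = 0;
  int pos = read0;  // clean-read coordinate
  auto push = [&](int o, int l) {
    if (l <= 0) return;
    if (!oo.empty() && oo.back() == o) ol.back() += l;
    else { oo.push_back(o); ol.push_back(l); }
  };
  for (int t = 0; t < op.size(); ++t) {
    int o = op[t], l = len[t];
    bool reads = (o == 0 || o == 1 || o == 3);
    if (!reads) {  // D: no read span, no edits inside
      push(o, l);
      continue;
    }
    int end = pos + l;
    while (l > 0) {
      // next edit inside [pos, end)
      while (e < edits.size() && edits[e].first < pos) ++e;
      if (e >= edits.size() || edits[e].first >= end) {
        push(o, l);
        pos = end; l = 0;
        break;
      }
      int ep = edits[e].first, et = edits[e].second;
      int pre = ep - pos;
      push(o, pre);
      if (et == 1) {
        // inserted base before ep: becomes I inside M, extends I/S
        push(o == 0 ? 1 : o, 1);
        push(o, 1);  // the original base at ep stays
      } else {
        // deleted base at ep: M -> D, I/S just shrink
        if (o == 0) push(2, 1);
      }
      l -= pre + 1;
      pos = ep + 1;
      ++e;
    }
  }
  return List::create(_["op"] = wrap(oo), _["len"] = wrap(ol));
}
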