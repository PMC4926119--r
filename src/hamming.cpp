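#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Best ungapped (Hamming) hit of each full-length tag against every
// equal-length window of every subject. If a tag is longer than a subject
// by <= len_tol, the subject is slid along the tag instead (isomiR ends).
// Ties: fewest mismatches, then first subject in file order, then
// leftmost position.
// [[Rcpp::export(name = ".hamming_scan_cpp")]]
List hamming_scan_cpp(CharacterVector tags, CharacterVector subjects,
                      int max_mismatch, int len_tol) {
  int nt = tags.size(), ns = subjects.size();
  IntegerVector best_idx(nt, NA_INTEGER), best_pos(nt, NA_INTEGER),
      best_mm(nt, NA_INTEGER), aln_len(nt, NA_INTEGER);
  std::vector<std::string> subs(ns);
  for (int k = 0; k < ns; ++k) subs[k] = as<std::string>(subjects[k]);
  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    int L = (int)tag.size();
    int bmm = max_mismatch + 1, bidx = -1, bpos = -1, blen = -1;
    for (int k = 0; k < ns && bmm > 0; ++k) {
      const std::string& sub = subs[k];
      int S = (int)sub.size();
      if (S >= L) {
        for (int p = 0; p + L <= S; ++p) {
          int mm = 0;
          for (int q = 0; q < L; ++q) {
            if (tag[q] != sub[p + q]) { if (++mm >= bmm) break; }
          }
          if (mm < bmm) { bmm = mm; bidx = k; bpos = p; blen = L;
                          if (bmm == 0) break; }
        }
      } else if (L - S <= len_tol) {
        for (int p = 0; p + S <= L; ++p) {
          int mm = 0;
          for (int q = 0; q < S; ++q) {
            if (sub[q] != tag[p + q]) { if (++mm >= bmm) break; }
          }
          if (mm < bmm) { bmm = mm; bidx = k; bpos = p; blen = S;
                          if (bmm == 0) break; }
        }
      }
    }
    if (bidx >= 0) {
      best_idx[t] = bidx + 1;  // 1-based for R
      best_pos[t] = bpos + 1;
      best_mm[t] = bmm;
      aln_len[t] = blen;
    }
  }
  return List::create(_["ref_index"] = best_idx, _["position"] = best_pos,
                      _["mismatches"] = best_mm, _["aln_length"] = aln_len);
}
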