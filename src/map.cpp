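// Ungapped mapping of peptide reads onto contigs.  A placement at a given
// offset (1-based contig coordinate of the read's first residue; may run off
// either contig end) is admissible when the overlapping portion is strictly
// more than min_portion of the read and carries at most max_mismatch
// substitutions.  'X' never matches anything, itself included.  The best
// placement per (read, contig) pair -- fewest mismatches, then longest
// overlap, then smallest offset -- is reported.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                        int max_mismatch, double min_portion) {
  const int nr = reads.size(), nc = contigs.size();
  std::vector<std::string> rs(nr), cs(nc);
  for (int i = 0; i < nr; ++i) rs[i] = as<std::string>(reads[i]);
  for (int i = 0; i < nc; ++i) cs[i] = as<std::string>(contigs[i]);
  std::vector<int> o_read, o_contig, o_off, o_mm, o_ov;
  for (int ri = 0; ri < nr; ++ri) {
    const std::string& r = rs[ri];
    const int m = (int) r.size();
    const int ov_min = (int) std::floor(min_portion * m) + 1;  // strict >
    if (ov_min > m) continue;
    for (int ci = 0; ci < nc; ++ci) {
      const std::string& c = cs[ci];
      const int L = (int) c.size();
      int best_mm = max_mismatch + 1, best_ov = -1, best_off = 0;
      for (int off = ov_min - m + 1; off <= L - ov_min + 1; ++off) {
        const int p0 = std::max(1, off), p1 = std::min(L, off + m - 1);
        const int ov = p1 - p0 + 1;
        if (ov < ov_min) continue;
        int mm = 0;
        for (int p = p0; p <= p1; ++p) {
          const char a = r[p - off], b = c[p - 1];
          if (a != b || a == 'X') {
            if (++mm > max_mismatch) break;
          }
        }
        if (mm > max_mismatch) continue;
        if (mm < best_mm || (mm == best_mm && ov > best_ov)) {
          best_mm = mm; best_ov = ov; best_off = off;
        }
      }
      if (best_ov >= 0) {
        o_read.push_back(ri + 1);
        o_contig.push_back(ci + 1);
        o_off.push_back(best_off);
        o_mm.push_back(best_mm);
        o_ov.push_back(best_ov);
      }
    }
  }
  return DataFrame::create(_["read"] = o_read, _["contig"] = o_contig,
                           _["offset"] = o_off, _["mismatches"] = o_mm,
                           _["overlap"] = o_ov);
}
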