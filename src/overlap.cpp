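// Exact suffix-prefix overlap links between reads (the overlap graph edges).
// For every ordered pair (r1, r2) the maximal overlap o with
// min_overlap <= o <= min(len1, len2) and o < len2 (a link must extend the
// contig by at least one residue) is reported.  Built via suffix-keyed
// hashing, not an all-pairs scan.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
using namespace Rcpp;

// [[Rcpp::export]]
DataFrame cpp_overlap_links(CharacterVector seqs, int min_overlap) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  int lmax = 0;
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    if ((int) s[i].size() > lmax) lmax = (int) s[i].size();
  }
  // prefix maps, one per overlap length
  std::vector<std::unordered_map<std::string, std::vector<int>>> pref(lmax + 1);
  for (int j = 0; j < n; ++j) {
    const int lj = (int) s[j].size();
    for (int o = min_overlap; o <= lj - 1; ++o)
      pref[o][s[j].substr(0, o)].push_back(j);
  }
  std::vector<int> from, to, ov;
  for (int i = 0; i < n; ++i) {
    const int li = (int) s[i].size();
    std::unordered_set<int> seen;
    int ohi = std::min(li, lmax - 1);
    for (int o = ohi; o >= min_overlap; --o) {
      auto it = pref[o].find(s[i].substr(li - o, o));
      if (it == pref[o].end()) continue;
      for (int j : it->second) {
        if (j == i || seen.count(j)) continue;
        seen.insert(j);
        from.push_back(i + 1);
        to.push_back(j + 1);
        ov.push_back(o);
      }
    }
  }
  return DataFrame::create(_["from"] = from, _["to"] = to, _["overlap"] = ov);
}
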