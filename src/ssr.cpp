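#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static bool is_primitive(const std::string &motif) {
  const int m = motif.size();
  for (int d = 1; d < m; ++d) {
    if (m % d != 0) continue;
    bool rep = true;
    for (int i = d; i < m && rep; ++i)
      if (motif[i] != motif[i - d]) rep = false;
    if (rep) return false;
  }
  return true;
}

static std::string min_rotation(const std::string &motif) {
  std::string best = motif, rot = motif;
  for (size_t r = 1; r < motif.size(); ++r) {
    std::rotate(rot.begin(), rot.begin() + 1, rot.end());
    if (rot < best) best = rot;
  }
  return best;
}

// Maximal perfect tandem repeats (microsatellites) with primitive motif of
// length 1..max_motif, total span >= max(min_total, 2*motif_len), no N.
// Partial trailing copies extend the span; copies = full copies.
// [[Rcpp::export]]
DataFrame find_ssrs_cpp(std::string seq, int min_total = 6, int max_motif = 8) {
  const int n = seq.size();
  std::vector<int> starts, ends, copies;
  std::vector<std::string> motifs;
  for (int m = 1; m <= max_motif; ++m) {
    int i = 0;
    while (i + m < n) {
      if (seq[i] == 'N' || seq[i] != seq[i + m]) { ++i; continue; }
      // run of period-m equalities starting at i
      int j = i;
      while (j + m < n && seq[j] != 'N' && seq[j + m] != 'N' &&
             seq[j] == seq[j + m])
        ++j;
      const int total = (j - i) + m; // span [i, i + total - 1]
      const int need = std::max(min_total, 2 * m);
      if (total >= need) {
        std::string motif = seq.substr(i, m);
        if (motif.find('N') == std::string::npos && is_primitive(motif)) {
          starts.push_back(i + 1);
          ends.push_back(i + total);
          motifs.push_back(min_rotation(motif));
          copies.push_back(total / m);
        }
      }
      i = j + 1;
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["motif"] = motifs, _["copies"] = copies,
                           _["stringsAsFactors"] = false);
}
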