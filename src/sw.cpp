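#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman with traceback. Scores: match > 0, mismatch < 0,
// gap_open / gap_extend are positive penalties (opening a gap of length L
// costs gap_open + L * gap_extend, BLAST convention).
// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s,
                  double match = 1.0, double mismatch = -2.0,
                  double gap_open = 5.0, double gap_extend = 2.0) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["aln_len"] = 0, _["matches"] = 0,
                        _["identity"] = NA_REAL, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER);
  const double NEG = -1e18;
  std::vector<double> M((n + 1) * (m + 1), 0.0), Ix((n + 1) * (m + 1), NEG),
      Iy((n + 1) * (m + 1), NEG);
  // traceback codes: 0 stop, 1 diag(M), 2 up(Ix: gap in s), 3 left(Iy: gap in q)
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0),
      tbX((n + 1) * (m + 1), 0), tbY((n + 1) * (m + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = i * (m + 1) + j, kd = (i - 1) * (m + 1) + (j - 1),
                ku = (i - 1) * (m + 1) + j, kl = i * (m + 1) + (j - 1);
      // gap in subject (consume query base): from M or extend Ix
      double openx = M[ku] - gap_open - gap_extend, extx = Ix[ku] - gap_extend;
      if (openx >= extx) { Ix[k] = openx; tbX[k] = 1; }
      else               { Ix[k] = extx;  tbX[k] = 2; }
      double openy = M[kl] - gap_open - gap_extend, exty = Iy[kl] - gap_extend;
      if (openy >= exty) { Iy[k] = openy; tbY[k] = 1; }
      else               { Iy[k] = exty;  tbY[k] = 3; }
      double sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      double diag = M[kd] + sub;
      double val = 0.0; unsigned char tb = 0;
      if (diag > val) { val = diag; tb = 1; }
      if (Ix[k] > val) { val = Ix[k]; tb = 2; }
      if (Iy[k] > val) { val = Iy[k]; tb = 3; }
      M[k] = val; tbM[k] = tb;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["aln_len"] = 0, _["matches"] = 0,
                        _["identity"] = NA_REAL, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER);
  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 0; // 0 = M, 2 = Ix, 3 = Iy
  int aln_len = 0, matches = 0;
  int qe = bi, se = bj, qs = bi, ss = bj;
  while (i > 0 && j > 0) {
    const int k = i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = tbM[k];
      if (tb == 0) break;
      if (tb == 1) {
        ++aln_len;
        if (q[i - 1] == s[j - 1]) ++matches;
        qs = i; ss = j; --i; --j;
      } else { state = tb; }
    } else if (state == 2) {
      ++aln_len; qs = i;
      unsigned char tb = tbX[k];
      --i; state = (tb == 1) ? 0 : 2;
    } else {
      ++aln_len; ss = j;
      unsigned char tb = tbY[k];
      --j; state = (tb == 1) ? 0 : 3;
    }
  }
  return List::create(
      _["score"] = best, _["aln_len"] = aln_len, _["matches"] = matches,
      _["identity"] = aln_len > 0 ? (double)matches / aln_len : NA_REAL,
      _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se);
}
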