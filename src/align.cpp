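#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// miRNA:target complementarity scoring (psRNATarget-style expectation penalty).
// The window is supplied in reverse-complement space, so a perfect target reads
// identically to the miRNA; a G:U wobble in the duplex appears as (m=G, w=A) or
// (m=T, w=C). Penalties: mismatch +1, wobble +0.5, gap +2; doubled when the
// miRNA position (1-based from the 5' end) lies in the seed [seed_start, seed_end].

static inline double sub_cost(char m, char w) {
  if (m == w) return 0.0;
  if ((m == 'G' && w == 'A') || (m == 'T' && w == 'C')) return 0.5;
  return 1.0;
}

static inline double seed_mul(int pos1, int seed_start, int seed_end) {
  return (pos1 >= seed_start && pos1 <= seed_end) ? 2.0 : 1.0;
}

static double align_cost(const std::string &m, const std::string &w,
                         double mismatch, double wobble, double gap,
                         int seed_start, int seed_end,
                         std::string *out_m, std::string *out_w, std::string *out_marks) {
  int nm = m.size(), nw = w.size();
  std::vector< std::vector<double> > D(nm + 1, std::vector<double>(nw + 1, 0.0));
  for (int i = 1; i <= nm; ++i)
    D[i][0] = D[i - 1][0] + gap * seed_mul(i, seed_start, seed_end);
  for (int j = 1; j <= nw; ++j)
    D[0][j] = D[0][j - 1] + gap * seed_mul(1, seed_start, seed_end);
  for (int i = 1; i <= nm; ++i) {
    double mul = seed_mul(i, seed_start, seed_end);
    for (int j = 1; j <= nw; ++j) {
      double s = sub_cost(m[i - 1], w[j - 1]);
      double cost_s = (s == 0.0) ? 0.0 : (s == 0.5 ? wobble : mismatch) * mul;
      double diag = D[i - 1][j - 1] + cost_s;
      double up   = D[i - 1][j] + gap * mul;        // gap in target
      double left = D[i][j - 1] + gap * mul;        // gap in miRNA
      double best = diag < up ? diag : up;
      if (left < best) best = left;
      D[i][j] = best;
    }
  }
  if (out_m != NULL) {
    // Traceback (diagonal preferred on ties).
    std::string am, aw, mk;
    int i = nm, j = nw;
    while (i > 0 || j > 0) {
      double mul = seed_mul(i > 0 ? i : 1, seed_start, seed_end);
      if (i > 0 && j > 0) {
        double s = sub_cost(m[i - 1], w[j - 1]);
        double cost_s = (s == 0.0) ? 0.0 : (s == 0.5 ? wobble : mismatch) * mul;
        if (D[i][j] == D[i - 1][j - 1] + cost_s) {
          am += m[i - 1]; aw += w[j - 1];
          mk += (s == 0.0) ? '|' : (s == 0.5 ? 'o' : ' ');
          --i; --j; continue;
        }
      }
      if (i > 0 && D[i][j] == D[i - 1][j] + gap * mul) {
        am += m[i - 1]; aw += '-'; mk += ' '; --i; continue;
      }
      am += '-'; aw += w[j - 1]; mk += ' '; --j;
    }
    std::reverse(am.begin(), am.end());
    std::reverse(aw.begin(), aw.end());
    std::reverse(mk.begin(), mk.end());
    *out_m = am; *out_w = aw; *out_marks = mk;
  }
  return D[nm][nw];
}

// [[Rcpp::export(name = ".align_site")]]
List align_site(std::string mirna, std::string window_rc,
                double mismatch, double wobble, double gap,
                int seed_start, int seed_end) {
  std::string am, aw, mk;
  double sc = align_cost(mirna, window_rc, mismatch, wobble, gap,
                         seed_start, seed_end, &am, &aw, &mk);
  return List::create(_["expectation"] = sc, _["mirna_aln"] = am,
                      _["window_aln"] = aw, _["marks"] = mk);
}

// Scan a transcript (plus strand, 5'->3') for target windows of the miRNA.
// transcript_rc must be the reverse complement of the transcript. For a window
// of length L starting at 0-based transcript position s, its reverse-complement
// is transcript_rc.substr(n - s - L, L). Scores windows of length nm and nm+1.
// [[Rcpp::export(name = ".scan_transcript")]]
List scan_transcript(std::string mirna, std::string transcript_rc,
                     double mismatch, double wobble, double gap,
                     int seed_start, int seed_end) {
  int n = transcript_rc.size(), nm = mirna.size();
  int n0 = n - nm + 1;       // starts for windows of length nm
  int n1 = n - nm;           // starts for windows of length nm + 1
  NumericVector s0(n0 > 0 ? n0 : 0), s1(n1 > 0 ? n1 : 0);
  for (int s = 0; s < n0; ++s) {
    std::string w = transcript_rc.substr(n - s - nm, nm);
    s0[s] = align_cost(mirna, w, mismatch, wobble, gap, seed_start, seed_end,
                       NULL, NULL, NULL);
  }
  for (int s = 0; s < n1; ++s) {
    std::string w = transcript_rc.substr(n - s - nm - 1, nm + 1);
    s1[s] = align_cost(mirna, w, mismatch, wobble, gap, seed_start, seed_end,
                       NULL, NULL, NULL);
  }
  return List::create(_["len_m"] = s0, _["len_m1"] = s1);
}
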