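#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pseudo-energy of a base pair: GC = -3, AU = -2, GU = -1 (kcal/mol), 0 if not pairable.
// Sequences arrive uppercased with T (not U).
static inline int pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1;
  return 0;
}

// Minimum-energy nested pairing (Nussinov-style DP with per-pair pseudo-energies).
// Hairpin loops must enclose >= min_loop unpaired bases. Traceback is deterministic:
// leaving i unpaired is preferred on ties, then the smallest pairing partner k.
// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);
  // E[i][j]: minimal energy of subsequence [i, j], 0-based inclusive.
  std::vector< std::vector<int> > E(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = E[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int e = pair_energy(seq[i], seq[k]);
        if (e == 0) continue;
        int inner = (k - i > 1) ? E[i + 1][k - 1] : 0;
        int rest  = (k < j) ? E[k + 1][j] : 0;
        int cand = e + inner + rest;
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }
  // Traceback.
  std::string db(n, '.');
  std::vector< std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (E[i][j] == E[i + 1][j]) {  // i unpaired preferred on ties
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int e = pair_energy(seq[i], seq[k]);
      if (e == 0) continue;
      int inner = (k - i > 1) ? E[i + 1][k - 1] : 0;
      int rest  = (k < j) ? E[k + 1][j] : 0;
      if (e + inner + rest == E[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k - i > 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = (double)E[0][n - 1]);
}
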