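#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Maximum base-pairing secondary structure (Nussinov recursion) with a
// minimum hairpin loop of `minloop` unpaired bases. Pairs allowed:
// Watson-Crick (A:U, G:C) and the G:U wobble. Ties are broken
// deterministically: pairing (i, j) is preferred over bifurcation, and the
// smallest split point wins.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int minloop) {
  int n = seq.size();
  std::vector<int> pt(n, -1); // 0-based partner table, -1 unpaired
  if (n > 1) {
    std::vector<std::vector<short> > M(n, std::vector<short>(n, 0));
    for (int len = minloop + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        short best = M[i][j - 1]; // j unpaired
        if (can_pair(seq[i], seq[j]) && j - i > minloop) {
          short v = (short)((i + 1 <= j - 1 ? M[i + 1][j - 1] : 0) + 1);
          if (v > best) best = v;
        }
        for (int k = i; k < j; ++k) {
          // k pairs with j
          if (can_pair(seq[k], seq[j]) && j - k > minloop) {
            short v = (short)((k > i ? M[i][k - 1] : 0) +
                              (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) + 1);
            if (v > best) best = v;
          }
        }
        M[i][j] = best;
      }
    }
    // iterative traceback
    std::vector<std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      if (i >= j || M[i][j] == 0) continue;
      if (M[i][j] == M[i][j - 1]) { // j unpaired
        stack.push_back(std::make_pair(i, j - 1));
        continue;
      }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        if (can_pair(seq[k], seq[j]) && j - k > minloop) {
          short v = (short)((k > i ? M[i][k - 1] : 0) +
                            (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) + 1);
          if (v == M[i][j]) {
            pt[k] = j; pt[j] = k;
            if (k > i) stack.push_back(std::make_pair(i, k - 1));
            if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
            done = true;
          }
        }
      }
    }
  }
  // dot-bracket and simple stacking energy: a pair stacked on an adjacent
  // pair contributes -3 (G:C), -2 (A:U) or -1 (G:U) kcal/mol.
  std::string db(n, '.');
  double energy = 0.0;
  int npairs = 0;
  for (int i = 0; i < n; ++i) {
    if (pt[i] > i) {
      db[i] = '('; db[pt[i]] = ')';
      ++npairs;
      bool stacked = (i + 1 < n && pt[i + 1] == pt[i] - 1) ||
                     (i > 0 && pt[i - 1] == pt[i] + 1);
      if (stacked) {
        char a = seq[i], b = seq[pt[i]];
        if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) energy -= 3.0;
        else if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) energy -= 2.0;
        else energy -= 1.0;
      }
    }
  }
  IntegerVector pt1(n);
  for (int i = 0; i < n; ++i) pt1[i] = pt[i] < 0 ? NA_INTEGER : pt[i] + 1;
  return List::create(_["structure"] = db, _["energy"] = energy,
                      _["pairs"] = npairs, _["pairtable"] = pt1);
}
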