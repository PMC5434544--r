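#include <Rcpp.h>
#include <vector>
#include <string>

// Weighted base-pair-maximization dynamic program over nested secondary
// structures (hairpin loops >= min_loop unpaired bases).  Pair weights are
// positive; the reported folding score is their negated sum, so more
// negative = more stable.  Traceback is deterministic: the 5'-most pairing
// partner achieving the optimum is preferred.

static inline int pair_w(char a, char b, int wGC, int wAU, int wGU) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return wAU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wGU;
  return 0;
}

// [[Rcpp::export]]
Rcpp::List nussinov_fold(std::string seq, int wGC, int wAU, int wGU,
                         int min_loop) {
  const int n = seq.size();
  std::string structure(n, '.');
  if (n == 0) {
    return Rcpp::List::create(Rcpp::Named("score") = 0,
                              Rcpp::Named("structure") = structure);
  }
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        const int w = pair_w(seq[k], seq[j], wGC, wAU, wGU);
        if (w == 0) continue;
        int v = w;
        if (k > i) v += M[i][k - 1];
        if (k + 1 <= j - 1) v += M[k + 1][j - 1];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // traceback (iterative; prefer pairing, 5'-most partner first)
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first;
    const int j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    const int target = M[i][j];
    bool paired = false;
    for (int k = i; k <= j - min_loop - 1; ++k) {
      const int w = pair_w(seq[k], seq[j], wGC, wAU, wGU);
      if (w == 0) continue;
      int v = w;
      if (k > i) v += M[i][k - 1];
      if (k + 1 <= j - 1) v += M[k + 1][j - 1];
      if (v == target) {
        structure[k] = '(';
        structure[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i, j - 1));
  }
  return Rcpp::List::create(Rcpp::Named("score") = -M[0][n - 1],
                            Rcpp::Named("structure") = structure);
}
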