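#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Watson-Crick plus GU wobble.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing structure (Nussinov DP) with a minimum hairpin loop
// size. Tie-break is deterministic: leaving position j unpaired is preferred
// over pairing it, and among pairings the smallest partner index k wins.
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
std::string nussinov_fold_cpp(std::string seq, int min_hairpin) {
  int n = seq.size();
  if (n == 0) return "";
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_hairpin + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];  // j unpaired
      for (int k = i; k <= j - min_hairpin - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int v = 1 + M[k + 1][j - 1] + (k > i ? M[i][k - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  std::string db(n, '.');
  // Iterative traceback mirroring the DP tie-break order.
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_hairpin + 1 || M[i][j] == 0) continue;
    if (M[i][j] == M[i][j - 1]) {  // prefer j unpaired
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_hairpin - 1; ++k) {  // earliest partner
      if (!can_pair(seq[k], seq[j])) continue;
      int v = 1 + M[k + 1][j - 1] + (k > i ? M[i][k - 1] : 0);
      if (v == M[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return db;
}
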