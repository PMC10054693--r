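#include <Rcpp.h>
#include <string>
#include <vector>

// Nussinov-style maximum base-pairing fold with a minimum hairpin size.
// DP over region scores; deterministic traceback: at each region [i, j]
// prefer leaving i unpaired, otherwise pair i with the smallest partner k
// attaining the optimum.

static inline bool can_pair(char a, char b, bool wobble) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if (wobble && ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'))) return true;
  return false;
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
Rcpp::String nussinov_cpp(std::string seq, int min_hairpin, bool wobble) {
  const int n = (int) seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      Rcpp::stop("sequence contains a residue outside {A,C,G,U}");
  }
  if (n == 0) return Rcpp::String("");
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_hairpin + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k], wobble)) continue;
        int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
        int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
        int cand = 1 + inner + outer;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_hairpin + 1) continue;
    if (M[i][j] == M[i + 1][j]) {  // prefer i unpaired
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_hairpin + 1; k <= j; ++k) {  // smallest partner wins
      if (!can_pair(seq[i], seq[k], wobble)) continue;
      int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
      int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
      if (1 + inner + outer == M[i][j]) {
        db[i] = '(';
        db[k] = ')';
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return Rcpp::String(db);
}
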