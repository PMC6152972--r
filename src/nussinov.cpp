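#include <Rcpp.h>
using namespace Rcpp;

// Pair weights favour stable stems: GC > AU > GU wobble.
static inline int pair_w(char a, char b, int wGC, int wAU, int wGU) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return wAU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wGU;
  return 0;
}

// Weighted Nussinov base-pair maximisation over nested structures.
// min_loop = minimum number of unpaired bases enclosed by any pair.
// Returns the optimal score and one optimal pairing (0-based partner
// index, -1 for unpaired). Traceback is deterministic and prefers
// pairing the leftmost base with its most distal admissible partner,
// which reconstructs hairpin stems outside-in when several structures
// tie on score.
// [[Rcpp::export]]
List nussinov_fold(std::string seq, int min_loop = 3,
                   int wGC = 3, int wAU = 2, int wGU = 1) {
  int n = (int) seq.size();
  IntegerVector pairing(n, -1);
  if (n == 0)
    return List::create(_["score"] = 0, _["pairing"] = pairing);

  std::vector< std::vector<int> > S(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = S[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_w(seq[i], seq[k], wGC, wAU, wGU);
        if (!w) continue;
        int s = w + (k - i >= 2 ? S[i + 1][k - 1] : 0)
                  + (k < j ? S[k + 1][j] : 0);
        if (s > best) best = s;
      }
      S[i][j] = best;
    }
  }

  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    bool paired_i = false;
    for (int k = j; k >= i + min_loop + 1; --k) {
      int w = pair_w(seq[i], seq[k], wGC, wAU, wGU);
      if (!w) continue;
      int s = w + (k - i >= 2 ? S[i + 1][k - 1] : 0)
                + (k < j ? S[k + 1][j] : 0);
      if (s == S[i][j]) {
        pairing[i] = k;
        pairing[k] = i;
        if (k - i >= 2) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        paired_i = true;
        break;
      }
    }
    if (!paired_i) stack.push_back(std::make_pair(i + 1, j));
  }
  return List::create(_["score"] = S[0][n - 1], _["pairing"] = pairing);
}
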