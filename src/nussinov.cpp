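#include <Rcpp.h>
using namespace Rcpp;

// Base-pair maximization over nested canonical structures.
// codes: 1=A, 2=C, 3=G, 4=U. Pair weights GC=3, AU=2, GU=1; other pairs
// are forbidden. Minimum hairpin loop of 3 unpaired nucleotides (j-i > 3).
// Traceback returns, among all maximum-score structures, the one whose
// pair set sorted by (i, j) is lexicographically smallest: at each interval
// the 5' end is paired whenever some optimal structure pairs it, to the
// smallest admissible partner.

static inline int pair_weight(int a, int b) {
  if ((a == 3 && b == 2) || (a == 2 && b == 3)) return 3; // G-C
  if ((a == 1 && b == 4) || (a == 4 && b == 1)) return 2; // A-U
  if ((a == 3 && b == 4) || (a == 4 && b == 3)) return 1; // G-U
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(IntegerVector codes, int min_loop = 3) {
  const int n = codes.size();
  // M[i][j] flattened, 0-based half-open logic on 1..n inclusive indices
  std::vector<int> M((size_t)(n + 2) * (n + 2), 0);
  auto idx = [n](int i, int j) { return (size_t)i * (n + 2) + j; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      int best = M[idx(i + 1, j)]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(codes[i - 1], codes[k - 1]);
        if (w == 0) continue;
        int cand = w + M[idx(i + 1, k - 1)] + M[idx(k + 1, j)];
        if (cand > best) best = cand;
      }
      M[idx(i, j)] = best;
    }
  }

  // traceback: stack of intervals, always resolving the leftmost end first
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(1, n));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    while (i < j && M[idx(i, j)] > 0) {
      int target = M[idx(i, j)];
      int chosen = 0;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(codes[i - 1], codes[k - 1]);
        if (w == 0) continue;
        if (w + M[idx(i + 1, k - 1)] + M[idx(k + 1, j)] == target) {
          chosen = k;
          break; // smallest partner wins the lexicographic tie-break
        }
      }
      if (chosen == 0) {
        ++i; // no optimal structure pairs i
      } else {
        pi.push_back(i);
        pj.push_back(chosen);
        if (chosen + 1 < j) stack.push_back(std::make_pair(chosen + 1, j));
        j = chosen - 1;
        ++i;
      }
    }
  }

  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  return List::create(_["score"] = (n > 0 ? M[idx(1, n)] : 0),
                      _["pairs"] = pairs);
}
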