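#include <Rcpp.h>
using namespace Rcpp;

// Stacking-aware maximum-score folding.
//
// V[i][j]: best score of region [i, j] given (i, j) paired (NEG if the two
// bases cannot pair or the loop would be too small).
// W[i][j]: best score of region [i, j], unconstrained.
// Pair scores GC=3, AU=2, GU=1; +1 for each stacked pair, i.e. a pair
// (i, j) whose inner neighbour (i+1, j-1) is also paired.

static const int NEG = -1000000000;

static inline int pair_score(int a, int b) {
  // codes: A=0, C=1, G=2, U=3
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1;
  return 0;
}

static void traceback_W(int i, int j, int min_loop,
                        const std::vector<std::vector<int> > &V,
                        const std::vector<std::vector<int> > &W,
                        const IntegerVector &s,
                        std::vector<int> &pairs);

static void traceback_V(int i, int j, int min_loop,
                        const std::vector<std::vector<int> > &V,
                        const std::vector<std::vector<int> > &W,
                        const IntegerVector &s,
                        std::vector<int> &pairs) {
  pairs.push_back(i);
  pairs.push_back(j);
  int ps = pair_score(s[i], s[j]);
  if (j - i - 2 < min_loop + 1) return;  // inner region cannot hold a pair
  // prefer the stacked continuation when it achieves the optimum
  if (V[i + 1][j - 1] > NEG && V[i][j] == ps + V[i + 1][j - 1] + 1) {
    traceback_V(i + 1, j - 1, min_loop, V, W, s, pairs);
  } else {
    traceback_W(i + 1, j - 1, min_loop, V, W, s, pairs);
  }
}

static void traceback_W(int i, int j, int min_loop,
                        const std::vector<std::vector<int> > &V,
                        const std::vector<std::vector<int> > &W,
                        const IntegerVector &s,
                        std::vector<int> &pairs) {
  while (i < j) {
    int best = W[i][j];
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (V[i][k] == NEG) continue;
      int rest = (k + 1 <= j) ? W[k + 1][j] : 0;
      if (V[i][k] + rest == best) {
        traceback_V(i, k, min_loop, V, W, s, pairs);
        i = k + 1;
        paired = true;
        break;
      }
    }
    if (!paired) ++i;  // i left unpaired
  }
}

// [[Rcpp::export]]
List fold_dp_cpp(IntegerVector s, int min_loop) {
  int n = s.size();
  std::vector<std::vector<int> > V(n, std::vector<int>(n, NEG));
  std::vector<std::vector<int> > W(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int ps = pair_score(s[i], s[j]);
      if (ps > 0) {
        int inner = 0;
        if (j - 1 - (i + 1) >= min_loop + 1) {
          inner = W[i + 1][j - 1];
          if (V[i + 1][j - 1] > NEG && V[i + 1][j - 1] + 1 > inner)
            inner = V[i + 1][j - 1] + 1;
        }
        V[i][j] = ps + inner;
      }
      int best = W[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (V[i][k] == NEG) continue;
        int rest = (k + 1 <= j) ? W[k + 1][j] : 0;
        if (V[i][k] + rest > best) best = V[i][k] + rest;
      }
      W[i][j] = best;
    }
  }
  std::vector<int> pairs;
  if (n > 1) traceback_W(0, n - 1, min_loop, V, W, s, pairs);
  return List::create(_["score"] = (n > 1 ? W[0][n - 1] : 0),
                      _["pairs"] = IntegerVector(pairs.begin(), pairs.end()));
}
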