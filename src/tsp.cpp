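#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Cost of the cyclic tour: sum of inverse distances over its edges.
static double tour_cost_inv(const std::vector<int>& ord,
                            const NumericMatrix& C) {
  const int n = ord.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += C(ord[i], ord[(i + 1) % n]);
  return s;
}

// Minimise the cyclic sum of inverse pairwise distances (so that mated
// couples are genetically distant).  Exact enumeration for n <= 8, else
// greedy construction from a capped set of starts followed by 2-opt with
// O(1) delta evaluation.  `Cinv` is the symmetric matrix of 1/max(d, eps).
// Returns the 1-based tour order.
// [[Rcpp::export]]
IntegerVector tsp_tour_cpp(const NumericMatrix& Cinv) {
  const int n = Cinv.nrow();
  std::vector<int> best(n), ord(n);
  double best_cost = R_PosInf;

  if (n <= 8) {
    std::vector<int> perm(n - 1);
    for (int i = 0; i < n - 1; ++i) perm[i] = i + 1;
    do {
      ord[0] = 0;
      std::copy(perm.begin(), perm.end(), ord.begin() + 1);
      const double c = tour_cost_inv(ord, Cinv);
      if (c < best_cost) { best_cost = c; best = ord; }
    } while (std::next_permutation(perm.begin(), perm.end()));
  } else {
    const int max_starts = std::min(n, 32);
    for (int s = 0; s < max_starts; ++s) {
      const int start = (int)((double)s * n / max_starts);
      std::vector<bool> used(n, false);
      ord[0] = start; used[start] = true;
      for (int k = 1; k < n; ++k) {
        int bestj = -1; double bc = R_PosInf;
        for (int j = 0; j < n; ++j) {
          if (!used[j] && Cinv(ord[k - 1], j) < bc) {
            bc = Cinv(ord[k - 1], j); bestj = j;
          }
        }
        ord[k] = bestj; used[bestj] = true;
      }
      const double c = tour_cost_inv(ord, Cinv);
      if (c < best_cost) { best_cost = c; best = ord; }
    }
    // 2-opt: reversing ord[i..j] swaps edges (i-1,i),(j,j+1) for
    // (i-1,j),(i,j+1); interior edges are unchanged by symmetry.
    bool improved = true;
    int passes = 0;
    ord = best;
    while (improved && passes++ < 100) {
      improved = false;
      for (int i = 0; i < n - 1; ++i) {
        const int prev = (i - 1 + n) % n;
        for (int j = i + 1; j < n; ++j) {
          const int next = (j + 1) % n;
          if (prev == j) continue;  // whole-cycle reversal is a no-op
          const double delta =
            Cinv(ord[prev], ord[j]) + Cinv(ord[i], ord[next]) -
            Cinv(ord[prev], ord[i]) - Cinv(ord[j], ord[next]);
          if (delta < -1e-12) {
            std::reverse(ord.begin() + i, ord.begin() + j + 1);
            improved = true;
          }
        }
      }
    }
    best = ord;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best[i] + 1;
  return out;
}
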