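#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Interval dynamic program over non-crossing structures with a minimum
// hairpin of 3 unpaired nucleotides (pairs require j - i > 3).
//
// E[i][j] = min( E[i+1][j],                                   i unpaired
//                min_k  e(i,k) + E[i+1][k-1] + E[k+1][j] )    i pairs k
//
// e(i,k) = base pair energy + dg[i] + dg[k] (per-pair pseudo-energy terms).
// Traceback ties prefer the pairing branch, then the smallest partner k, so
// outputs are deterministic.

static const double INF = std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

// [[Rcpp::export]]
List fold_reference_cpp(IntegerVector seq_codes, NumericVector dg,
                        NumericMatrix pair_energy, int min_sep) {
  const int n = seq_codes.size();
  const bool has_dg = dg.size() == n;
  std::vector<std::vector<double>> E(n + 2, std::vector<double>(n + 1, 0.0));

  auto pe = [&](int i, int k) -> double {  // 0-based
    double e = pair_energy(seq_codes[i], seq_codes[k]);
    if (!R_finite(e)) return INF;
    if (has_dg) e += dg[i] + dg[k];
    return e;
  };

  // E indexed 1-based: E[i][j] over region i..j, j < i -> 0
  for (int i = n; i >= 1; --i) {
    for (int j = i; j <= n; ++j) {
      double best = E[i + 1][j];
      for (int k = i + min_sep + 1; k <= j; ++k) {
        double e = pe(i - 1, k - 1);
        if (e == INF) continue;
        double cand = e + E[i + 1][k - 1] + E[k + 1][j];
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }

  // traceback
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int>> stack;
  stack.push_back({1, n});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    double target = E[i][j];
    bool paired = false;
    for (int k = i + min_sep + 1; k <= j; ++k) {  // smallest k first
      double e = pe(i - 1, k - 1);
      if (e == INF) continue;
      if (e + E[i + 1][k - 1] + E[k + 1][j] <= target + EPS) {
        pi.push_back(i); pj.push_back(k);
        stack.push_back({i + 1, k - 1});
        stack.push_back({k + 1, j});
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back({i + 1, j});
  }

  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  return List::create(_["pairs"] = pairs, _["score"] = E[1][n]);
}

// Maximum-cardinality non-crossing subset of a given pair set, by the same
// interval DP restricted to the listed candidate pairs. Used to strip
// pseudoknots deterministically before tree encoding.
// [[Rcpp::export]]
IntegerMatrix max_noncross_subset_cpp(int n, IntegerMatrix pairs) {
  std::vector<std::vector<int>> partner(n + 1);
  for (int r = 0; r < pairs.nrow(); ++r)
    partner[pairs(r, 0)].push_back(pairs(r, 1));
  for (int i = 1; i <= n; ++i)                       // deterministic traceback
    std::sort(partner[i].begin(), partner[i].end());

  std::vector<std::vector<int>> S(n + 2, std::vector<int>(n + 1, 0));
  for (int i = n; i >= 1; --i)
    for (int j = i; j <= n; ++j) {
      int best = S[i + 1][j];
      for (int k : partner[i])
        if (k <= j) {
          int cand = 1 + S[i + 1][k - 1] + S[k + 1][j];
          if (cand > best) best = cand;
        }
      S[i][j] = best;
    }

  std::vector<int> pi, pj;
  std::vector<std::pair<int, int>> stack;
  stack.push_back({1, n});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    bool paired = false;
    for (int k : partner[i])
      if (k <= j && 1 + S[i + 1][k - 1] + S[k + 1][j] == S[i][j]) {
        pi.push_back(i); pj.push_back(k);
        stack.push_back({i + 1, k - 1});
        stack.push_back({k + 1, j});
        paired = true;
        break;
      }
    if (!paired) stack.push_back({i + 1, j});
  }

  IntegerMatrix out(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    out(r, 0) = pi[r];
    out(r, 1) = pj[r];
  }
  return out;
}
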