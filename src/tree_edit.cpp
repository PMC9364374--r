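#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Zhang-Shasha ordered tree edit distance with unit insert/delete costs and
// relabel cost 1 for differing labels (0 otherwise).
//
// Trees arrive as postorder label vectors plus, for each node, the postorder
// index of its leftmost leaf descendant (1-based). Keyroots are the nodes
// with no left sibling on the path to the root, i.e. nodes whose leftmost
// leaf differs from their parent's.

static void keyroots(const IntegerVector &lml, std::vector<int> &kr) {
  int n = lml.size();
  std::vector<bool> seen(n + 1, false);
  for (int i = n; i >= 1; --i) {       // rightmost node of each lml class
    if (!seen[lml[i - 1]]) {
      kr.push_back(i);
      seen[lml[i - 1]] = true;
    }
  }
  std::sort(kr.begin(), kr.end());
}

// [[Rcpp::export]]
double tree_edit_distance_cpp(IntegerVector labels1, IntegerVector lml1,
                              IntegerVector labels2, IntegerVector lml2) {
  const int n1 = labels1.size(), n2 = labels2.size();
  if (n1 == 0) return n2;
  if (n2 == 0) return n1;

  std::vector<int> kr1, kr2;
  keyroots(lml1, kr1);
  keyroots(lml2, kr2);

  std::vector<std::vector<double>> td(n1 + 1, std::vector<double>(n2 + 1, 0.0));
  // forest distance scratch, indexed from lml-1 .. i
  std::vector<std::vector<double>> fd(n1 + 2, std::vector<double>(n2 + 2, 0.0));

  auto gamma = [&](int a, int b) { return labels1[a - 1] == labels2[b - 1] ? 0.0 : 1.0; };

  for (int x : kr1) {
    int lx = lml1[x - 1];
    for (int y : kr2) {
      int ly = lml2[y - 1];
      fd[lx - 1][ly - 1] = 0.0;
      for (int i = lx; i <= x; ++i) fd[i][ly - 1] = fd[i - 1][ly - 1] + 1.0;
      for (int j = ly; j <= y; ++j) fd[lx - 1][j] = fd[lx - 1][j - 1] + 1.0;
      for (int i = lx; i <= x; ++i) {
        for (int j = ly; j <= y; ++j) {
          if (lml1[i - 1] == lx && lml2[j - 1] == ly) {
            double d = std::min({fd[i - 1][j] + 1.0, fd[i][j - 1] + 1.0,
                                 fd[i - 1][j - 1] + gamma(i, j)});
            fd[i][j] = d;
            td[i][j] = d;
          } else {
            fd[i][j] = std::min({fd[i - 1][j] + 1.0, fd[i][j - 1] + 1.0,
                                 fd[lml1[i - 1] - 1][lml2[j - 1] - 1] + td[i][j]});
          }
        }
      }
    }
  }
  return td[n1][n2];
}
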