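#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Simplified nearest-neighbour folding.
//
// Energy model (kept deliberately small so tests can hand-sum it):
//   pair strength  G:C = 3.0, A:U = 2.0, G:U = 1.0  (kcal/mol units)
//   stack of two adjacent pairs contributes -(s1 + s2) / 2
//   isolated pairs, loops and exterior bases contribute 0
//   minimum hairpin loop size = 3 nt, no pseudoknots
//
// The MFE of a perfect helix of pairs p1..pk is therefore
//   -sum_{i=1}^{k-1} (s(p_i) + s(p_{i+1})) / 2.

static inline int nt_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

static inline double pair_strength(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.0; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2.0; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.0; // G:U
  return 0.0;
}

static inline bool can_pair(int a, int b) {
  return a >= 0 && b >= 0 && pair_strength(a, b) > 0.0;
}

static const double INF = 1e9;
static const int MINLOOP = 3;

// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(std::string seq) {
  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = nt_code(seq[i]);

  // W[i][j]: minimum energy of subsequence i..j (any structure)
  // V[i][j]: minimum energy of i..j given that (i, j) is paired
  std::vector< std::vector<double> > W(n, std::vector<double>(n, 0.0));
  std::vector< std::vector<double> > V(n, std::vector<double>(n, INF));

  for (int len = MINLOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (can_pair(s[i], s[j]) && j - i - 1 >= MINLOOP) {
        double v = W[i + 1][j - 1];
        if (can_pair(s[i + 1], s[j - 1]) && (j - 1) - (i + 1) - 1 >= MINLOOP &&
            V[i + 1][j - 1] < INF / 2) {
          double stacked = V[i + 1][j - 1] -
            (pair_strength(s[i], s[j]) + pair_strength(s[i + 1], s[j - 1])) / 2.0;
          if (stacked < v) v = stacked;
        }
        V[i][j] = v;
      }
      double w = W[i + 1][j];
      if (W[i][j - 1] < w) w = W[i][j - 1];
      if (V[i][j] < w) w = V[i][j];
      for (int k = i + 1; k < j - 1; ++k) {
        double split = W[i][k] + W[k + 1][j];
        if (split < w) w = split;
      }
      W[i][j] = w;
    }
  }

  // traceback; preference order makes ties deterministic and leaves
  // energetically neutral bases unpaired
  std::vector<int> partner(n, -1);
  std::stack< std::pair<std::pair<int,int>, bool> > todo; // ((i,j), via_V)
  if (n >= MINLOOP + 2) todo.push(std::make_pair(std::make_pair(0, n - 1), false));
  while (!todo.empty()) {
    std::pair<std::pair<int,int>, bool> top = todo.top(); todo.pop();
    int i = top.first.first, j = top.first.second;
    bool via_v = top.second;
    if (j - i + 1 < MINLOOP + 2) continue;
    if (via_v) {
      partner[i] = j; partner[j] = i;
      if (can_pair(s[i + 1], s[j - 1]) && (j - 1) - (i + 1) - 1 >= MINLOOP &&
          V[i + 1][j - 1] < INF / 2) {
        double stacked = V[i + 1][j - 1] -
          (pair_strength(s[i], s[j]) + pair_strength(s[i + 1], s[j - 1])) / 2.0;
        if (stacked == V[i][j]) {
          todo.push(std::make_pair(std::make_pair(i + 1, j - 1), true));
          continue;
        }
      }
      todo.push(std::make_pair(std::make_pair(i + 1, j - 1), false));
      continue;
    }
    double w = W[i][j];
    if (w == W[i + 1][j]) {
      todo.push(std::make_pair(std::make_pair(i + 1, j), false));
    } else if (w == W[i][j - 1]) {
      todo.push(std::make_pair(std::make_pair(i, j - 1), false));
    } else if (V[i][j] < INF / 2 && w == V[i][j]) {
      todo.push(std::make_pair(std::make_pair(i, j), true));
    } else {
      bool done = false;
      for (int k = i + 1; k < j - 1 && !done; ++k) {
        if (w == W[i][k] + W[k + 1][j]) {
          todo.push(std::make_pair(std::make_pair(i, k), false));
          todo.push(std::make_pair(std::make_pair(k + 1, j), false));
          done = true;
        }
      }
    }
  }

  std::string db(n, '.');
  IntegerVector pairs(n, 0);
  for (int i = 0; i < n; ++i) {
    if (partner[i] >= 0) {
      db[i] = (partner[i] > i) ? '(' : ')';
      pairs[i] = partner[i] + 1; // 1-based
    }
  }
  double mfe = (n >= 2) ? W[0][n - 1] : 0.0;
  return List::create(_["structure"] = db, _["mfe"] = mfe, _["pairs"] = pairs);
}
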