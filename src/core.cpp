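#include <Rcpp.h>
#include <string>
#include <vector>
#include <stack>
using namespace Rcpp;

// Allowed pairs for the baseline folder: Watson-Crick plus G.T wobble.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Maximum-cardinality nested pairing (Nussinov) with a minimum hairpin loop.
// Traceback is deterministic: at each interval the 5' base is paired with the
// largest admissible partner that achieves the optimum, otherwise left
// unpaired. Returns the 1-based partner vector (0 = unpaired).
// [[Rcpp::export(name = ".nussinov_fold")]]
IntegerVector nussinov_fold(std::string seq, int min_loop) {
  int n = seq.size();
  IntegerVector partner(n, 0);
  if (n < min_loop + 2) return partner;
  // N[i][j] over 0-based half-open logic: score of interval [i, j]
  std::vector< std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int i = n - 2; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) {
      int best = N[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int cand = 1;
        if (i + 1 <= k - 1) cand += N[i + 1][k - 1];
        if (k + 1 <= j) cand += N[k + 1][j];
        if (cand > best) best = cand;
      }
      N[i][j] = best;
    }
  }
  std::stack< std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    std::pair<int, int> iv = todo.top(); todo.pop();
    int i = iv.first, j = iv.second;
    if (i >= j) continue;
    int target = N[i][j];
    int chosen = -1;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int cand = 1;
      if (i + 1 <= k - 1) cand += N[i + 1][k - 1];
      if (k + 1 <= j) cand += N[k + 1][j];
      if (cand == target) { chosen = k; break; }
    }
    if (chosen >= 0) {
      partner[i] = chosen + 1;
      partner[chosen] = i + 1;
      if (i + 1 <= chosen - 1) todo.push(std::make_pair(i + 1, chosen - 1));
      if (chosen + 1 <= j) todo.push(std::make_pair(chosen + 1, j));
    } else {
      todo.push(std::make_pair(i + 1, j));
    }
  }
  return partner;
}

// Global affine-gap alignment (Gotoh). A gap of length L costs
// gap_open + gap_extend * L. Ties in the traceback prefer diagonal, then a
// gap in the second string (up), then a gap in the first (left).
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, double match, double mismatch,
                 double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  const double NEG = -1e18;
  std::vector< std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector< std::vector<double> > X(n + 1, std::vector<double>(m + 1, NEG)); // gap in b
  std::vector< std::vector<double> > Y(n + 1, std::vector<double>(m + 1, NEG)); // gap in a
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = -(gap_open + gap_extend * i);
  for (int j = 1; j <= m; ++j) Y[0][j] = -(gap_open + gap_extend * j);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double dm = std::max(M[i - 1][j - 1], std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = s + dm;
      X[i][j] = std::max(std::max(M[i - 1][j] - gap_open, X[i - 1][j]),
                         Y[i - 1][j] - gap_open) - gap_extend;
      Y[i][j] = std::max(std::max(M[i][j - 1] - gap_open, X[i][j - 1] - gap_open),
                         Y[i][j - 1]) - gap_extend;
    }
  }
  double score = std::max(M[n][m], std::max(X[n][m], Y[n][m]));
  // traceback with explicit state, tie order M > X > Y
  int i = n, j = m;
  int state;
  if (M[n][m] >= X[n][m] && M[n][m] >= Y[n][m]) state = 0;
  else if (X[n][m] >= Y[n][m]) state = 1;
  else state = 2;
  std::string ra, rb;
  const double EPS = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; continue; }
    if (j == 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue; }
    if (state == 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      double need = M[i][j] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[i][j] - need) < EPS) state = 0;
      else if (std::abs(X[i][j] - need) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      double need = X[i][j] + gap_extend;
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M[i][j] - gap_open - need) < EPS) state = 0;
      else if (std::abs(X[i][j] - need) < EPS) state = 1;
      else state = 2;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double need = Y[i][j] + gap_extend;
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[i][j] - gap_open - need) < EPS) state = 0;
      else if (std::abs(X[i][j] - gap_open - need) < EPS) state = 1;
      else state = 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}

// Profile-profile global affine alignment over the 7-letter structural
// alphabet. Profiles are 7 x ncol frequency matrices (gaps excluded from the
// rows; column sums may be < 1 when gaps are present). Returns the move path:
// 0 = take a column from both, 1 = column from A only, 2 = from B only.
// [[Rcpp::export(name = ".profile_align")]]
List profile_align(NumericMatrix A, NumericMatrix B, double match,
                   double mismatch, double gap_open, double gap_extend) {
  int n = A.ncol(), m = B.ncol(), K = A.nrow();
  const double NEG = -1e18;
  std::vector< std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector< std::vector<double> > X(n + 1, std::vector<double>(m + 1, NEG));
  std::vector< std::vector<double> > Y(n + 1, std::vector<double>(m + 1, NEG));
  // precompute column-column scores
  std::vector<double> sumA(n, 0.0), sumB(m, 0.0);
  for (int i = 0; i < n; ++i) for (int k = 0; k < K; ++k) sumA[i] += A(k, i);
  for (int j = 0; j < m; ++j) for (int k = 0; k < K; ++k) sumB[j] += B(k, j);
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = -(gap_open + gap_extend * i);
  for (int j = 1; j <= m; ++j) Y[0][j] = -(gap_open + gap_extend * j);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dot = 0.0;
      for (int k = 0; k < K; ++k) dot += A(k, i - 1) * B(k, j - 1);
      double s = match * dot + mismatch * (sumA[i - 1] * sumB[j - 1] - dot);
      double dm = std::max(M[i - 1][j - 1], std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = s + dm;
      X[i][j] = std::max(std::max(M[i - 1][j] - gap_open, X[i - 1][j]),
                         Y[i - 1][j] - gap_open) - gap_extend;
      Y[i][j] = std::max(std::max(M[i][j - 1] - gap_open, X[i][j - 1] - gap_open),
                         Y[i][j - 1]) - gap_extend;
    }
  }
  double score = std::max(M[n][m], std::max(X[n][m], Y[n][m]));
  int i = n, j = m, state;
  if (M[n][m] >= X[n][m] && M[n][m] >= Y[n][m]) state = 0;
  else if (X[n][m] >= Y[n][m]) state = 1;
  else state = 2;
  std::vector<int> path;
  const double EPS = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { path.push_back(2); --j; continue; }
    if (j == 0) { path.push_back(1); --i; continue; }
    if (state == 0) {
      double dot = 0.0;
      for (int k = 0; k < K; ++k) dot += A(k, i - 1) * B(k, j - 1);
      double s = match * dot + mismatch * (sumA[i - 1] * sumB[j - 1] - dot);
      path.push_back(0);
      double need = M[i][j] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[i][j] - need) < EPS) state = 0;
      else if (std::abs(X[i][j] - need) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) {
      path.push_back(1);
      double need = X[i][j] + gap_extend;
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M[i][j] - gap_open - need) < EPS) state = 0;
      else if (std::abs(X[i][j] - need) < EPS) state = 1;
      else state = 2;
    } else {
      path.push_back(2);
      double need = Y[i][j] + gap_extend;
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[i][j] - gap_open - need) < EPS) state = 0;
      else if (std::abs(X[i][j] - gap_open - need) < EPS) state = 1;
      else state = 2;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["path"] = wrap(path), _["score"] = score);
}
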