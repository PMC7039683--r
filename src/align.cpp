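// Affine-gap global alignment (Needleman-Wunsch with Gotoh's three-state
// recursion) plus sequence-vs-profile alignment for progressive three-way
// alignments.  A gap of length g costs gap_open + (g - 1) * gap_extend.
// Tie-breaking during traceback is deterministic: diagonal (match or
// mismatch) is preferred, then a gap in the second sequence, then a gap in
// the first.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// state 0 = M (diagonal), 1 = X (gap in b: consumes a), 2 = Y (gap in a)
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG)),
      X = M, Y = M;
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      M[i][j] = s + std::max(M[i - 1][j - 1], std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      X[i][j] = std::max(M[i - 1][j] + gap_open,
                         std::max(X[i - 1][j] + gap_extend, Y[i - 1][j] + gap_open));
      Y[i][j] = std::max(M[i][j - 1] + gap_open,
                         std::max(X[i][j - 1] + gap_open, Y[i][j - 1] + gap_extend));
    }
  }
  double best = std::max(M[n][m], std::max(X[n][m], Y[n][m]));
  int state = (M[n][m] >= X[n][m] && M[n][m] >= Y[n][m]) ? 0
              : (X[n][m] >= Y[n][m] ? 1 : 2);
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double prev = M[i][j] - s;
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] == prev) state = 0;
      else if (X[i][j] == prev) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in b
      double cur = X[i][j];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (X[i][j] + gap_extend == cur) state = 1;
      else state = 2;
    } else { // gap in a
      double cur = Y[i][j];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (X[i][j] + gap_open == cur) state = 1;
      else state = 2;
    }
    if (i == 0 && j == 0) break;
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = best);
}

// Align sequence c against a fixed 2-row profile (aligned strings with '-').
// Column-vs-base score = mean over rows of (match / mismatch); a '-' row
// character scores as mismatch.  Gap columns inserted into the profile add
// '-' to both rows but are penalized once.
// [[Rcpp::export]]
List nw_profile_cpp(std::vector<std::string> profile, std::string c, double match,
                    double mismatch, double gap_open, double gap_extend) {
  if (profile.size() < 1) stop("empty profile");
  const int n = (int)profile[0].size(), m = (int)c.size();
  const int R = (int)profile.size();
  for (int r = 1; r < R; ++r)
    if ((int)profile[r].size() != n) stop("profile rows differ in length");
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG)),
      X = M, Y = M;
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + (j - 1) * gap_extend;
  auto colscore = [&](int i, char x) {
    double s = 0.0;
    for (int r = 0; r < R; ++r) {
      char p = profile[r][i - 1];
      s += (p != '-' && p == x) ? match : mismatch;
    }
    return s / R;
  };
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = colscore(i, c[j - 1]);
      M[i][j] = s + std::max(M[i - 1][j - 1], std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      X[i][j] = std::max(M[i - 1][j] + gap_open,
                         std::max(X[i - 1][j] + gap_extend, Y[i - 1][j] + gap_open));
      Y[i][j] = std::max(M[i][j - 1] + gap_open,
                         std::max(X[i][j - 1] + gap_open, Y[i][j - 1] + gap_extend));
    }
  }
  double best = std::max(M[n][m], std::max(X[n][m], Y[n][m]));
  int state = (M[n][m] >= X[n][m] && M[n][m] >= Y[n][m]) ? 0
              : (X[n][m] >= Y[n][m] ? 1 : 2);
  std::vector<std::string> rows(R);
  std::string rc;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = colscore(i, c[j - 1]);
      double prev = M[i][j] - s;
      for (int r = 0; r < R; ++r) rows[r].push_back(profile[r][i - 1]);
      rc.push_back(c[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] == prev) state = 0;
      else if (X[i][j] == prev) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in c
      double cur = X[i][j];
      for (int r = 0; r < R; ++r) rows[r].push_back(profile[r][i - 1]);
      rc.push_back('-');
      --i;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (X[i][j] + gap_extend == cur) state = 1;
      else state = 2;
    } else { // gap column in the profile
      double cur = Y[i][j];
      for (int r = 0; r < R; ++r) rows[r].push_back('-');
      rc.push_back(c[j - 1]);
      --j;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (X[i][j] + gap_open == cur) state = 1;
      else state = 2;
    }
    if (i == 0 && j == 0) break;
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
  }
  for (int r = 0; r < R; ++r) std::reverse(rows[r].begin(), rows[r].end());
  std::reverse(rc.begin(), rc.end());
  CharacterVector out(R + 1);
  for (int r = 0; r < R; ++r) out[r] = rows[r];
  out[R] = rc;
  return List::create(_["rows"] = out, _["score"] = best);
}
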