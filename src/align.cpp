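// Affine-gap pairwise alignment (Needleman-Wunsch-Gotoh and Smith-Waterman)
// with a fixed, fully deterministic traceback.  Conventions:
//   * a is the "query", b the "subject".
//   * A gap run of length L costs gap_open + L * gap_extend (open <= 0,
//     extend <= 0), charged once per run plus once per gap column.
//   * Tie-break at every choice: diagonal (M) > up (gap in b, consumes a)
//     > left (gap in a, consumes b).
#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (up, gap in b), 2 = Y (left, gap in a)

// [[Rcpp::export(name = ".cpp_align_global")]]
List cpp_align_global(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF);
  std::vector<double> X((n + 1) * W, NEG_INF);
  std::vector<double> Y((n + 1) * W, NEG_INF);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) Y[j] = gap_open + j * gap_extend;

  for (int i = 1; i <= n; ++i) {
    int r = i * W, p = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double dM = M[p + j - 1], dX = X[p + j - 1], dY = Y[p + j - 1];
      double best = dM;
      if (dX > best) best = dX;
      if (dY > best) best = dY;
      M[r + j] = (best == NEG_INF) ? NEG_INF : s + best;

      double xM = M[p + j] + gap_open + gap_extend;
      double xX = X[p + j] + gap_extend;
      double xY = Y[p + j] + gap_open + gap_extend;
      X[r + j] = std::max(xM, std::max(xX, xY));

      double yM = M[r + j - 1] + gap_open + gap_extend;
      double yX = X[r + j - 1] + gap_open + gap_extend;
      double yY = Y[r + j - 1] + gap_extend;
      Y[r + j] = std::max(yM, std::max(yX, yY));
    }
  }

  // traceback: prefer M > X > Y
  std::string a_aln, b_aln;
  int i = n, j = m;
  int state = 0;
  double fin[3] = { M[n * W + m], X[n * W + m], Y[n * W + m] };
  if (fin[1] > fin[state]) state = 1;
  if (fin[2] > fin[state]) state = 2;
  double score = fin[state];

  while (i > 0 || j > 0) {
    int r = i * W, p = (i - 1) * W;
    if (state == 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      a_aln.push_back(a[i - 1]);
      b_aln.push_back(b[j - 1]);
      double target = M[r + j] - s;
      int prev = 2;
      if (M[p + j - 1] == target) prev = 0;
      else if (X[p + j - 1] == target) prev = 1;
      --i; --j;
      state = prev;
    } else if (state == 1) {
      a_aln.push_back(a[i - 1]);
      b_aln.push_back('-');
      int prev;
      if (M[p + j] + gap_open + gap_extend == X[r + j]) prev = 0;
      else if (X[p + j] + gap_extend == X[r + j]) prev = 1;
      else prev = 2;
      --i;
      state = prev;
    } else {
      a_aln.push_back('-');
      b_aln.push_back(b[j - 1]);
      int prev;
      if (M[r + j - 1] + gap_open + gap_extend == Y[r + j]) prev = 0;
      else if (X[r + j - 1] + gap_open + gap_extend == Y[r + j]) prev = 1;
      else prev = 2;
      --j;
      state = prev;
    }
  }
  std::reverse(a_aln.begin(), a_aln.end());
  std::reverse(b_aln.begin(), b_aln.end());
  return List::create(_["score"] = score,
                      _["a_aln"] = a_aln, _["b_aln"] = b_aln,
                      _["q_start"] = 0, _["q_end"] = n,
                      _["s_start"] = 0, _["s_end"] = m);
}

// [[Rcpp::export(name = ".cpp_align_local")]]
List cpp_align_local(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF);
  std::vector<double> X((n + 1) * W, NEG_INF);
  std::vector<double> Y((n + 1) * W, NEG_INF);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int r = i * W, p = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double pre = 0.0;  // fresh local alignment start
      double dM = M[p + j - 1], dX = X[p + j - 1], dY = Y[p + j - 1];
      if (dM > pre) pre = dM;
      if (dX > pre) pre = dX;
      if (dY > pre) pre = dY;
      M[r + j] = s + pre;

      double xM = M[p + j] + gap_open + gap_extend;
      double xX = X[p + j] + gap_extend;
      double xY = Y[p + j] + gap_open + gap_extend;
      X[r + j] = std::max(xM, std::max(xX, xY));

      double yM = M[r + j - 1] + gap_open + gap_extend;
      double yX = X[r + j - 1] + gap_open + gap_extend;
      double yY = Y[r + j - 1] + gap_extend;
      Y[r + j] = std::max(yM, std::max(yX, yY));

      if (M[r + j] > best) { best = M[r + j]; bi = i; bj = j; }
    }
  }

  std::string a_aln, b_aln;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;
    q_end = bi; s_end = bj;
    while (state != -1) {
      int r = i * W, p = (i - 1) * W;
      if (state == 0) {
        double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
        a_aln.push_back(a[i - 1]);
        b_aln.push_back(b[j - 1]);
        double pre = M[r + j] - s;
        double pM = M[p + j - 1], pX = X[p + j - 1], pY = Y[p + j - 1];
        --i; --j;
        // prefer stopping on a zero remainder (shortest optimal alignment)
        if (pre == 0.0) state = -1;
        else if (pM == pre) state = 0;
        else if (pX == pre) state = 1;
        else if (pY == pre) state = 2;
        else state = -1;
      } else if (state == 1) {
        a_aln.push_back(a[i - 1]);
        b_aln.push_back('-');
        int prev;
        if (M[p + j] + gap_open + gap_extend == X[r + j]) prev = 0;
        else if (X[p + j] + gap_extend == X[r + j]) prev = 1;
        else prev = 2;
        --i;
        state = prev;
      } else {
        a_aln.push_back('-');
        b_aln.push_back(b[j - 1]);
        int prev;
        if (M[r + j - 1] + gap_open + gap_extend == Y[r + j]) prev = 0;
        else if (X[r + j - 1] + gap_open + gap_extend == Y[r + j]) prev = 1;
        else prev = 2;
        --j;
        state = prev;
      }
    }
    q_start = i; s_start = j;
    std::reverse(a_aln.begin(), a_aln.end());
    std::reverse(b_aln.begin(), b_aln.end());
  }
  return List::create(_["score"] = best,
                      _["a_aln"] = a_aln, _["b_aln"] = b_aln,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["s_start"] = s_start, _["s_end"] = s_end);
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration reference: walks every gapped alignment (every
// monotone path of diagonal/up/left ops, with affine run state) and returns
// the best total score.  No memoisation -- this is the brute-force oracle the
// dynamic programs are validated against on short sequences.
static double enum_best(const std::string &a, const std::string &b,
                        int i, int j, int state,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  if (i == n && j == m) return 0.0;
  double best = NEG_INF;
  if (i < n && j < m) {
    double s = (a[i] == b[j]) ? match : mismatch;
    double v = s + enum_best(a, b, i + 1, j + 1, 0, match, mismatch,
                             gap_open, gap_extend);
    if (v > best) best = v;
  }
  if (i < n) {
    double cost = (state == 1) ? gap_extend : gap_open + gap_extend;
    double v = cost + enum_best(a, b, i + 1, j, 1, match, mismatch,
                                gap_open, gap_extend);
    if (v > best) best = v;
  }
  if (j < m) {
    double cost = (state == 2) ? gap_extend : gap_open + gap_extend;
    double v = cost + enum_best(a, b, i, j + 1, 2, match, mismatch,
                                gap_open, gap_extend);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_enum_global_score")]]
double cpp_enum_global_score(std::string a, std::string b,
                             double match, double mismatch,
                             double gap_open, double gap_extend) {
  return enum_best(a, b, 0, 0, -1, match, mismatch, gap_open, gap_extend);
}

// [[Rcpp::export(name = ".cpp_enum_local_score")]]
double cpp_enum_local_score(std::string a, std::string b,
                            double match, double mismatch,
                            double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  double best = 0.0;  // empty alignment always admissible
  for (int i1 = 0; i1 < n; ++i1) {
    for (int i2 = i1 + 1; i2 <= n; ++i2) {
      std::string sa = a.substr(i1, i2 - i1);
      for (int j1 = 0; j1 < m; ++j1) {
        for (int j2 = j1 + 1; j2 <= m; ++j2) {
          std::string sb = b.substr(j1, j2 - j1);
          double v = enum_best(sa, sb, 0, 0, -1, match, mismatch,
                               gap_open, gap_extend);
          if (v > best) best = v;
        }
      }
    }
  }
  return best;
}
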