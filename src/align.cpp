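// Affine-gap pairwise alignment (Gotoh) with deterministic traceback,
// plus a score-only kernel reused by the composition-preserving shuffle null.
//
// Sequences arrive as 0-based integer codes into the score matrix S.
// Gap of length k costs gap_open + k * gap_extend (the BLAST 11/1 convention).
// All scores are integer-valued; doubles are exact here, so == comparisons
// in the traceback are safe.

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG = -1e18;

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// [[Rcpp::export(name = ".gotoh_local")]]
List gotoh_local(IntegerVector a, IntegerVector b, NumericMatrix S,
                 double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double go = gap_open + gap_extend; // cost of opening a length-1 gap
  const double ge = gap_extend;

  // state matrices, (m+1) x (n+1); M = aligned column, Ix = gap in target
  // (consumes query), Iy = gap in query (consumes target)
  std::vector<double> M((m + 1) * (n + 1), NEG);
  std::vector<double> Ix((m + 1) * (n + 1), NEG);
  std::vector<double> Iy((m + 1) * (n + 1), NEG);
  const int W = n + 1;
#define IDX(i, j) ((i) * W + (j))

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double diag = 0.0;
      if (i > 1 || j > 1) {
        double pm = M[IDX(i - 1, j - 1)];
        double px = Ix[IDX(i - 1, j - 1)];
        double py = Iy[IDX(i - 1, j - 1)];
        diag = std::max(0.0, max3(pm, px, py));
      }
      M[IDX(i, j)] = S(a[i - 1], b[j - 1]) + diag;
      double xo = M[IDX(i - 1, j)] - go;
      double xe = Ix[IDX(i - 1, j)] - ge;
      Ix[IDX(i, j)] = std::max(xo, xe);
      double yo = M[IDX(i, j - 1)] - go;
      double ye = Iy[IDX(i, j - 1)] - ge;
      Iy[IDX(i, j)] = std::max(yo, ye);
      // strict > keeps the smallest (query end, target end) among ties
      if (M[IDX(i, j)] > best) {
        best = M[IDX(i, j)];
        bi = i;
        bj = j;
      }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["path"] = "",
                        _["qstart"] = 0, _["tstart"] = 0);
  }

  // traceback from (bi, bj) in state M; among equal predecessors prefer
  // M > Ix > Iy; stop as soon as the remaining prefix contributes 0
  std::string path;
  int i = bi, j = bj, state = 0; // 0=M, 1=Ix, 2=Iy
  while (true) {
    if (state == 0) {
      path.push_back('M');
      double diag = M[IDX(i, j)] - S(a[i - 1], b[j - 1]);
      --i; --j;
      if (diag <= 0.0 || i < 1 || j < 1) break;
      if (M[IDX(i, j)] == diag) state = 0;
      else if (Ix[IDX(i, j)] == diag) state = 1;
      else if (Iy[IDX(i, j)] == diag) state = 2;
      else break; // diag realized by the fresh-start option
    } else if (state == 1) {
      path.push_back('D');
      double here = Ix[IDX(i, j)];
      if (M[IDX(i - 1, j)] - go == here) { state = 0; }
      else { state = 1; }
      --i;
    } else {
      path.push_back('I');
      double here = Iy[IDX(i, j)];
      if (M[IDX(i, j - 1)] - go == here) { state = 0; }
      else { state = 2; }
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = best, _["path"] = path,
                      _["qstart"] = i, _["tstart"] = j);
#undef IDX
}

// [[Rcpp::export(name = ".gotoh_global")]]
List gotoh_global(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double go = gap_open + gap_extend;
  const double ge = gap_extend;

  std::vector<double> M((m + 1) * (n + 1), NEG);
  std::vector<double> Ix((m + 1) * (n + 1), NEG);
  std::vector<double> Iy((m + 1) * (n + 1), NEG);
  const int W = n + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) Ix[IDX(i, 0)] = -(gap_open + i * ge);
  for (int j = 1; j <= n; ++j) Iy[IDX(0, j)] = -(gap_open + j * ge);

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double diag = max3(M[IDX(i - 1, j - 1)], Ix[IDX(i - 1, j - 1)],
                         Iy[IDX(i - 1, j - 1)]);
      M[IDX(i, j)] = S(a[i - 1], b[j - 1]) + diag;
      Ix[IDX(i, j)] = std::max(M[IDX(i - 1, j)] - go, Ix[IDX(i - 1, j)] - ge);
      Iy[IDX(i, j)] = std::max(M[IDX(i, j - 1)] - go, Iy[IDX(i, j - 1)] - ge);
    }
  }

  double sm = M[IDX(m, n)], sx = Ix[IDX(m, n)], sy = Iy[IDX(m, n)];
  double best = max3(sm, sx, sy);
  int state = (sm == best) ? 0 : (sx == best ? 1 : 2);

  std::string path;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back('M');
      double diag = M[IDX(i, j)] - S(a[i - 1], b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[IDX(i, j)] == diag) state = 0;
      else if (Ix[IDX(i, j)] == diag) state = 1;
      else state = 2;
    } else if (state == 1) {
      path.push_back('D');
      double here = Ix[IDX(i, j)];
      state = (M[IDX(i - 1, j)] - go == here) ? 0 : 1;
      --i;
    } else {
      path.push_back('I');
      double here = Iy[IDX(i, j)];
      state = (M[IDX(i, j - 1)] - go == here) ? 0 : 2;
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = best, _["path"] = path,
                      _["qstart"] = 0, _["tstart"] = 0);
#undef IDX
}

// score-only Smith-Waterman, rolling-row Gotoh over a flattened score table
// (T is row-major 21x21: T[21*a + b]); the caller provides six row buffers
// of length n+1
static double sw_score_only(const int *a, int m, const int *b, int n,
                            const double *T, double go, double ge,
                            double *M0, double *X0, double *Y0,
                            double *M1, double *X1, double *Y1) {
  for (int j = 0; j <= n; ++j) {
    M0[j] = NEG;
    X0[j] = NEG;
    Y0[j] = NEG;
  }
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    const double *Sr = T + 21 * a[i - 1];
    M1[0] = NEG;
    X1[0] = NEG;
    Y1[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      double diag = M0[j - 1];
      if (X0[j - 1] > diag) diag = X0[j - 1];
      if (Y0[j - 1] > diag) diag = Y0[j - 1];
      if (diag < 0.0) diag = 0.0;
      const double mij = Sr[b[j - 1]] + diag;
      const double xo = M0[j] - go, xe = X0[j] - ge;
      const double yo = M1[j - 1] - go, ye = Y1[j - 1] - ge;
      M1[j] = mij;
      X1[j] = xo > xe ? xo : xe;
      Y1[j] = yo > ye ? yo : ye;
      if (mij > best) best = mij;
    }
    std::swap(M0, M1);
    std::swap(X0, X1);
    std::swap(Y0, Y1);
  }
  return best;
}

// flatten the 21x21 score matrix to row-major C layout
static std::vector<double> flatten_scores(const NumericMatrix &S) {
  std::vector<double> T(21 * 21);
  for (int r = 0; r < 21; ++r)
    for (int c = 0; c < 21; ++c)
      T[21 * r + c] = S(r, c);
  return T;
}

// [[Rcpp::export(name = ".sw_score")]]
double sw_score(IntegerVector a, IntegerVector b, NumericMatrix S,
                double gap_open, double gap_extend) {
  std::vector<double> T = flatten_scores(S);
  const int n = b.size();
  std::vector<double> buf(6 * (n + 1));
  double *p = buf.data();
  return sw_score_only(a.begin(), a.size(), b.begin(), n, T.data(),
                       gap_open + gap_extend, gap_extend,
                       p, p + (n + 1), p + 2 * (n + 1), p + 3 * (n + 1),
                       p + 4 * (n + 1), p + 5 * (n + 1));
}

// Best local score against n_shuffles composition-preserving shuffles of b.
// Uses R's RNG (Fisher-Yates), so results follow set.seed() in R.
// [[Rcpp::export(name = ".shuffled_scores")]]
NumericVector shuffled_scores(IntegerVector a, IntegerVector b,
                              NumericMatrix S, double gap_open,
                              double gap_extend, int n_shuffles) {
  const double go = gap_open + gap_extend, ge = gap_extend;
  const int n = b.size();
  std::vector<double> T = flatten_scores(S);
  std::vector<int> perm(b.begin(), b.end());
  std::vector<double> buf(6 * (n + 1));
  double *p = buf.data();
  NumericVector out(n_shuffles);
  for (int s = 0; s < n_shuffles; ++s) {
    for (int k = n - 1; k > 0; --k) {
      int r = (int)std::floor(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(perm[k], perm[r]);
    }
    out[s] = sw_score_only(a.begin(), a.size(), perm.data(), n, T.data(),
                           go, ge, p, p + (n + 1), p + 2 * (n + 1),
                           p + 3 * (n + 1), p + 4 * (n + 1),
                           p + 5 * (n + 1));
  }
  return out;
}
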