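#include <Rcpp.h>
using namespace Rcpp;

// Residues are encoded 0..19 in the package's fixed alphabet order; any
// negative code (unknown residue, gap) contributes nothing to a score.

// [[Rcpp::export]]
NumericVector pssm_window_scores_cpp(IntegerVector seq, NumericMatrix weights) {
  int w = weights.nrow(), L = seq.size();
  int nwin = L - w + 1;
  if (nwin < 1) return NumericVector(0);
  NumericVector out(nwin);
  for (int s = 0; s < nwin; ++s) {
    double sc = 0.0;
    for (int j = 0; j < w; ++j) {
      int a = seq[s + j];
      if (a >= 0) sc += weights(j, a);
    }
    out[s] = sc;
  }
  return out;
}

// Best window score of each shuffled sequence. perms is n_shuffles x L of
// 1-based permutation indices (generated with R's RNG so seeding stays on
// the R side).
// [[Rcpp::export]]
NumericVector pssm_null_best_cpp(IntegerVector seq, NumericMatrix weights,
                                 IntegerMatrix perms) {
  int w = weights.nrow(), L = seq.size();
  int nwin = L - w + 1;
  int n = perms.nrow();
  NumericVector out(n);
  if (nwin < 1) return out;
  std::vector<int> shuf(L);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < L; ++i) shuf[i] = seq[perms(r, i) - 1];
    double best = R_NegInf;
    for (int s = 0; s < nwin; ++s) {
      double sc = 0.0;
      for (int j = 0; j < w; ++j) {
        int a = shuf[s + j];
        if (a >= 0) sc += weights(j, a);
      }
      if (sc > best) best = sc;
    }
    out[r] = best;
  }
  return out;
}

static inline double best3(double m, double y, double x, int &which) {
  // deterministic preference: diagonal (0) over gap-in-A (1) over gap-in-B (2)
  double b = m;
  which = 0;
  if (y > b) { b = y; which = 1; }
  if (x > b) { b = x; which = 2; }
  return b;
}

// Gotoh global alignment of two profiles with affine gaps.
// ca, cb: 20 x L residue-count matrices (one column per profile column);
// submat: 20 x 20 substitution scores; na, nb: number of rows per profile.
// Column-pair score = ca_i' S cb_j / (na * nb); a gap run of length g costs
// gap_open + (g - 1) * gap_extend.
// Returns 1-based column indices of each profile along the merged alignment,
// 0 marking a gap column.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix ca, NumericMatrix cb, NumericMatrix submat,
                       double gap_open, double gap_extend,
                       double na_rows, double nb_rows) {
  const int La = ca.ncol(), Lb = cb.ncol();
  const double NEG = -1e30;
  const double denom = na_rows * nb_rows;

  // P = S * cb, so score(i, j) = dot(ca[, i], P[, j]) / denom
  NumericMatrix P(20, Lb);
  for (int j = 0; j < Lb; ++j)
    for (int a = 0; a < 20; ++a) {
      double s = 0.0;
      for (int b = 0; b < 20; ++b) s += submat(a, b) * cb(b, j);
      P(a, j) = s;
    }

  NumericMatrix M(La + 1, Lb + 1), Y(La + 1, Lb + 1), X(La + 1, Lb + 1);
  IntegerMatrix tbM(La + 1, Lb + 1), tbY(La + 1, Lb + 1), tbX(La + 1, Lb + 1);

  M(0, 0) = 0.0; Y(0, 0) = NEG; X(0, 0) = NEG;
  for (int j = 1; j <= Lb; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + (j - 1) * gap_extend);
    tbY(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= La; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + (i - 1) * gap_extend);
    tbX(i, 0) = (i == 1) ? 0 : 2;
  }

  int w;
  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < 20; ++a) s += ca(a, i - 1) * P(a, j - 1);
      s /= denom;
      M(i, j) = s + best3(M(i - 1, j - 1), Y(i - 1, j - 1), X(i - 1, j - 1), w);
      tbM(i, j) = w;
      Y(i, j) = best3(M(i, j - 1) - gap_open, Y(i, j - 1) - gap_extend,
                      X(i, j - 1) - gap_open, w);
      tbY(i, j) = w;
      X(i, j) = best3(M(i - 1, j) - gap_open, Y(i - 1, j) - gap_open,
                      X(i - 1, j) - gap_extend, w);
      tbX(i, j) = w;
    }
  }

  int state;
  double score = best3(M(La, Lb), Y(La, Lb), X(La, Lb), state);

  std::vector<int> ai, bi;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      state = tbM(i, j); --i; --j;
    } else if (state == 1) {
      ai.push_back(0); bi.push_back(j);
      state = tbY(i, j); --j;
    } else {
      ai.push_back(i); bi.push_back(0);
      state = tbX(i, j); --i;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = score,
                      _["a_cols"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_cols"] = IntegerVector(bi.begin(), bi.end()));
}

// Pairwise-deletion p-distance over a chosen column subset (1-based indices,
// possibly with repeats, as in a bootstrap replicate). aln is n x L of residue
// codes with negatives marking gaps/unknowns. Pairs with zero comparable
// columns come back NA for the caller to handle.
// [[Rcpp::export]]
NumericMatrix pdist_cpp(IntegerMatrix aln, IntegerVector cols) {
  int n = aln.nrow(), nc = cols.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int comp = 0, mis = 0;
      for (int k = 0; k < nc; ++k) {
        int c = cols[k] - 1;
        int a = aln(i, c), b = aln(j, c);
        if (a >= 0 && b >= 0) {
          ++comp;
          if (a != b) ++mis;
        }
      }
      double d = comp > 0 ? (double)mis / comp : NA_REAL;
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
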