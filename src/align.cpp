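#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment of two column profiles.
//
// profA, profB: nres x L count matrices (residue counts per alignment
// column; gaps carry no count). submat: nres x nres substitution scores.
// Column-column score is mean-of-pairs: (cA' S cB) / (nA * nB).
// Gap cost for a run of length L is open + ext*(L-1): the first gap column
// of a run costs `open`, each further column `ext`. Terminal gaps are
// penalized like internal ones.
//
// Traceback tie-break on equal score: diagonal (match/mismatch) first, then
// a gap in the first profile (consuming a column of B), then a gap in the
// second profile. This makes the alignment fully deterministic.
//
// Returns list(score, path): path entries 0 = consume both, 1 = consume A
// only (gap in B), 2 = consume B only (gap in A), ordered start to end.
// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(NumericMatrix profA, NumericMatrix profB,
                        NumericMatrix submat, double nA, double nB,
                        double open, double ext) {
  const int La = profA.ncol(), Lb = profB.ncol(), R = submat.nrow();
  const double NEG = -1e30;

  // precompute column-column scores
  NumericMatrix cs(La, Lb);
  {
    // SB = S %*% profB  (R x Lb)
    std::vector<double> SB((size_t)R * Lb, 0.0);
    for (int j = 0; j < Lb; ++j)
      for (int r = 0; r < R; ++r) {
        double acc = 0.0;
        for (int q = 0; q < R; ++q) acc += submat(r, q) * profB(q, j);
        SB[(size_t)r + (size_t)R * j] = acc;
      }
    const double denom = nA * nB;
    for (int i = 0; i < La; ++i)
      for (int j = 0; j < Lb; ++j) {
        double acc = 0.0;
        for (int r = 0; r < R; ++r)
          acc += profA(r, i) * SB[(size_t)r + (size_t)R * j];
        cs(i, j) = acc / denom;
      }
  }

  const size_t W = (size_t)Lb + 1;
  std::vector<double> M((La + 1) * W, NEG), Ix((La + 1) * W, NEG),
      Iy((La + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= La; ++i) Ix[(size_t)i * W] = -(open + ext * (i - 1));
  for (int j = 1; j <= Lb; ++j) Iy[(size_t)j] = -(open + ext * (j - 1));

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      const size_t c = (size_t)i * W + j, d = (size_t)(i - 1) * W + (j - 1),
                   u = (size_t)(i - 1) * W + j, l = (size_t)i * W + (j - 1);
      double best = M[d];
      if (Ix[d] > best) best = Ix[d];
      if (Iy[d] > best) best = Iy[d];
      M[c] = best + cs(i - 1, j - 1);
      // Ix: gap column in B, consuming column i of A
      double ix = M[u] - open;
      if (Ix[u] - ext > ix) ix = Ix[u] - ext;
      if (Iy[u] - open > ix) ix = Iy[u] - open;
      Ix[c] = ix;
      // Iy: gap column in A, consuming column j of B
      double iy = M[l] - open;
      if (Iy[l] - ext > iy) iy = Iy[l] - ext;
      if (Ix[l] - open > iy) iy = Ix[l] - open;
      Iy[c] = iy;
    }
  }

  const size_t endc = (size_t)La * W + Lb;
  // pick3: argmax with fixed preference M > Ix > Iy; mirrors the forward
  // max so traceback never needs floating-point equality tests
  auto pick3 = [](double m, double ix, double iy) {
    if (m >= ix && m >= iy) return 0;
    if (ix >= iy) return 1;
    return 2;
  };
  int state = pick3(M[endc], Ix[endc], Iy[endc]);
  double score = (state == 0) ? M[endc] : (state == 1 ? Ix[endc] : Iy[endc]);
  if (La == 0 && Lb == 0) { state = 0; score = 0.0; }

  std::vector<int> path;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(0);
      const size_t d = (size_t)(i - 1) * W + (j - 1);
      state = pick3(M[d], Ix[d], Iy[d]);
      --i; --j;
    } else if (state == 1) {  // consumed column i of A, gap in B
      path.push_back(1);
      const size_t u = (size_t)(i - 1) * W + j;
      state = pick3(M[u] - open, Ix[u] - ext, Iy[u] - open);
      --i;
    } else {  // consumed column j of B, gap in A
      path.push_back(2);
      const size_t l = (size_t)i * W + (j - 1);
      state = pick3(M[l] - open, Ix[l] - open, Iy[l] - ext);
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score, _["path"] = wrap(path));
}
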