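// Profile-profile global alignment with affine gaps (Gotoh), the merge step
// of the progressive multiple aligner.  Column-pair substitution score is the
// average pairwise score over non-gap residues; existing gaps score 0.
// Deterministic tie-breaking: M > X (gap in B) > Y (gap in A).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstring>
using namespace Rcpp;

static inline int enc(char ch) {
  switch (ch) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case '-': return 5;
    default: return 4;
  }
}

static const double NEG = -1e30;

// [[Rcpp::export(name = ".align_profiles_cpp")]]
CharacterVector align_profiles_cpp(std::vector<std::string> A,
                                   std::vector<std::string> B, double match,
                                   double mismatch, double gap_open,
                                   double gap_ext) {
  int nA = (int)A.size(), nB = (int)B.size();
  if (nA == 0 || nB == 0) stop("empty profile");
  int LA = (int)A[0].size(), LB = (int)B[0].size();
  for (auto& r : A)
    if ((int)r.size() != LA) stop("ragged profile A");
  for (auto& r : B)
    if ((int)r.size() != LB) stop("ragged profile B");
  if ((double)(LA + 1) * (LB + 1) > 3e8)
    stop("profiles too long to align");

  // residue counts per column (A,C,G,T,N); gaps excluded
  std::vector<std::array<double, 5>> cA(LA), cB(LB);
  for (auto& a : cA) a.fill(0.0);
  for (auto& a : cB) a.fill(0.0);
  for (int r = 0; r < nA; ++r)
    for (int i = 0; i < LA; ++i) {
      int b = enc(A[r][i]);
      if (b < 5) cA[i][b] += 1.0;
    }
  for (int r = 0; r < nB; ++r)
    for (int j = 0; j < LB; ++j) {
      int b = enc(B[r][j]);
      if (b < 5) cB[j][b] += 1.0;
    }
  double denom = (double)nA * nB;

  auto sub = [&](int i, int j) {
    const auto& a = cA[i];
    const auto& b = cB[j];
    double sm = 0.0, tot_a = 0.0, tot_b = 0.0;
    for (int z = 0; z < 5; ++z) { tot_a += a[z]; tot_b += b[z]; }
    double mpairs = 0.0;
    for (int z = 0; z < 4; ++z) mpairs += a[z] * b[z];  // N never matches
    double allpairs = tot_a * tot_b;
    sm = mpairs * match + (allpairs - mpairs) * mismatch;
    return sm / denom;
  };

  size_t W = (size_t)LB + 1;
  std::vector<double> M((LA + 1) * W, NEG), X((LA + 1) * W, NEG),
      Y((LA + 1) * W, NEG);
  // traceback: 2 bits per matrix packed in one byte
  std::vector<unsigned char> tb((LA + 1) * W, 0);
  auto TB = [&](int i, int j) -> unsigned char& { return tb[i * W + j]; };
  auto at = [&](std::vector<double>& Mx, int i, int j) -> double& {
    return Mx[i * W + j];
  };
  at(M, 0, 0) = 0.0;
  for (int i = 1; i <= LA; ++i) {
    at(X, i, 0) = gap_open + (i - 1) * gap_ext;
    TB(i, 0) |= (1 << 2);  // X came from X
  }
  for (int j = 1; j <= LB; ++j) {
    at(Y, 0, j) = gap_open + (j - 1) * gap_ext;
    TB(0, j) |= (1 << 4);  // Y came from Y
  }
  for (int i = 1; i <= LA; ++i) {
    for (int j = 1; j <= LB; ++j) {
      // M from best of (M,X,Y)[i-1][j-1]
      double m0 = at(M, i - 1, j - 1), x0 = at(X, i - 1, j - 1),
             y0 = at(Y, i - 1, j - 1);
      int src = 0; double best = m0;
      if (x0 > best) { best = x0; src = 1; }
      if (y0 > best) { best = y0; src = 2; }
      at(M, i, j) = best + sub(i - 1, j - 1);
      TB(i, j) |= (unsigned char)src;
      // X: consume column of A, gap in B
      double xo = at(M, i - 1, j) + gap_open, xe = at(X, i - 1, j) + gap_ext,
             xy = at(Y, i - 1, j) + gap_open;
      int sx = 0; double bx = xo;
      if (xe > bx) { bx = xe; sx = 1; }
      if (xy > bx) { bx = xy; sx = 2; }
      at(X, i, j) = bx;
      TB(i, j) |= (unsigned char)(sx << 2);
      // Y: consume column of B, gap in A
      double yo = at(M, i, j - 1) + gap_open, ye = at(Y, i, j - 1) + gap_ext,
             yx = at(X, i, j - 1) + gap_open;
      int sy = 0; double by = yo;
      if (ye > by) { by = ye; sy = 1; }
      if (yx > by) { by = yx; sy = 2; }
      at(Y, i, j) = by;
      TB(i, j) |= (unsigned char)(sy << 4);
    }
  }
  // traceback from the best end state, preference M > X > Y
  int state = 0;
  double bm = at(M, LA, LB), bx = at(X, LA, LB), by = at(Y, LA, LB);
  if (bx > bm && bx >= by) state = 1;
  else if (by > bm && by > bx) state = 2;
  std::string moves;  // 'D' consume both, 'U' consume A (gap B), 'L' gap A
  int i = LA, j = LB;
  while (i > 0 || j > 0) {
    if (i == 0) { moves.push_back('L'); --j; continue; }
    if (j == 0) { moves.push_back('U'); --i; continue; }
    unsigned char t = TB(i, j);
    if (state == 0) {
      int src = t & 3;
      moves.push_back('D'); --i; --j;
      state = src;
    } else if (state == 1) {
      int src = (t >> 2) & 3;
      moves.push_back('U'); --i;
      state = (src == 0) ? 0 : (src == 1 ? 1 : 2);
    } else {
      int src = (t >> 4) & 3;
      moves.push_back('L'); --j;
      state = (src == 0) ? 0 : (src == 1 ? 2 : 1);
    }
  }
  std::reverse(moves.begin(), moves.end());
  int L = (int)moves.size();
  CharacterVector res(nA + nB);
  for (int r = 0; r < nA; ++r) {
    std::string s(L, '-');
    int p = 0;
    for (int t = 0; t < L; ++t)
      if (moves[t] != 'L') s[t] = A[r][p++];
    res[r] = s;
  }
  for (int r = 0; r < nB; ++r) {
    std::string s(L, '-');
    int p = 0;
    for (int t = 0; t < L; ++t)
      if (moves[t] != 'U') s[t] = B[r][p++];
    res[nA + r] = s;
  }
  return res;
}
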