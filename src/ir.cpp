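// Inverted-repeat (IR) pair detection on a circular genome.
//
// A pair of disjoint intervals (B, A) with sequence(A) == revcomp(sequence(B))
// up to a mismatch budget lies on a single "anti-diagonal" of the circle:
// every base pairing (x, y) of the repeat satisfies x + y == c (mod n) for a
// constant c.  Maximal pairs are therefore maximal match-windows on one of the
// two mirror arcs of an anti-diagonal.  The detector seeds anti-diagonals with
// exact k-mer hits (subquadratic); the brute-force oracle enumerates every
// anchor position pair directly from the definition and is kept independent of
// the seeded path.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int enc(char ch) {
  switch (ch) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}
static inline int cmp4(int b) { return b < 4 ? 3 - b : 4; }

struct IRHit {
  int s1, s2, len, mm;
  bool valid;
  IRHit() : s1(0), s2(0), len(0), mm(0), valid(false) {}
};

// order: longer, then fewer mismatches, then smaller start coordinate
static inline bool better(const IRHit& a, const IRHit& b) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.len != b.len) return a.len > b.len;
  if (a.mm != b.mm) return a.mm < b.mm;
  int amin = std::min(a.s1, a.s2), bmin = std::min(b.s1, b.s2);
  if (amin != bmin) return amin < bmin;
  return std::max(a.s1, a.s2) < std::max(b.s1, b.s2);
}

static inline void consider(IRHit& best, int ws, int we, int c, int n, int mm) {
  int L = we - ws + 1;
  IRHit h;
  h.s1 = ((ws % n) + n) % n;
  int s2 = (((c - we) % n) + n) % n;
  h.s2 = s2;
  h.len = L; h.mm = mm; h.valid = true;
  if (h.s2 < h.s1) std::swap(h.s1, h.s2);
  if (better(h, best)) best = h;
}

// Scan one anti-diagonal c: the valid window domain is the open arc
// (c/2, c/2 + n/2); windows there are automatically disjoint from (or
// abutting) their mirror copy.
static void scan_antidiagonal(const std::vector<int>& s, int n, int c,
                              int min_len, int max_mm, IRHit& best) {
  // integer domain: lo..hi with c/2 < x < c/2 + n/2 (real bounds)
  int lo = c / 2 + 1;                 // smallest integer > c/2
  if (c % 2 != 0) lo = (c + 1) / 2;   // c odd: > c/2 means >= (c+1)/2
  double b2 = c / 2.0 + n / 2.0;
  int hi = (int)std::ceil(b2) - 1;    // largest integer < b2
  if (hi - lo + 1 < min_len) return;

  // mismatch positions along the arc (sentinels at lo-1 and hi+1)
  std::vector<int> mm;
  mm.push_back(lo - 1);
  for (int x = lo; x <= hi; ++x) {
    int a = s[x % n];
    int b = s[((c - x) % n + n) % n];
    if (a >= 4 || b >= 4 || a != cmp4(b)) mm.push_back(x);
  }
  mm.push_back(hi + 1);
  int nmm = (int)mm.size() - 2;
  if (nmm <= max_mm) {
    if (hi - lo + 1 >= min_len) consider(best, lo, hi, c, n, nmm);
    return;
  }
  for (int t = 0; t + max_mm + 1 < (int)mm.size(); ++t) {
    int ws = mm[t] + 1;
    int we = mm[t + max_mm + 1] - 1;
    if (we - ws + 1 >= min_len) consider(best, ws, we, c, n, max_mm);
  }
}

static IRHit detect_core(const std::vector<int>& s, int n, int min_len,
                         int max_mm) {
  IRHit best;
  int k = (min_len - max_mm) / (max_mm + 1);
  if (k > 20) k = 20;
  if (k < 4 || n < 2 * k) {
    for (int c = 0; c < n; ++c)
      scan_antidiagonal(s, n, c, min_len, max_mm, best);
    return best;
  }
  // k-mer index over the circle
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(n * 2);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t v = 0; int run = 0;
  for (int q = 0; q < n + k - 1; ++q) {
    int b = s[q % n];
    if (b >= 4) { run = 0; v = 0; continue; }
    v = ((v << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      int start = q - k + 1;
      if (start < n) idx[v].push_back(start);
    }
  }
  std::unordered_set<int> cset;
  uint64_t rc = 0; run = 0;
  for (int q = 0; q < n + k - 1; ++q) {
    int b = s[q % n];
    if (b >= 4) { run = 0; rc = 0; continue; }
    // reverse-complement k-mer built incrementally: prepend complement
    rc = (rc >> 2) | ((uint64_t)cmp4(b) << (2 * (k - 1)));
    if (++run >= k) {
      int i = q - k + 1;
      if (i >= n) continue;
      auto it = idx.find(rc);
      if (it == idx.end()) continue;
      for (int q2 : it->second) {
        int c = (int)(((long long)i + q2 + k - 1) % n);
        cset.insert(c);
        if ((int)cset.size() > n) break;
      }
      if ((int)cset.size() > n) break;
    }
  }
  if ((int)cset.size() > n) {
    for (int c = 0; c < n; ++c)
      scan_antidiagonal(s, n, c, min_len, max_mm, best);
  } else {
    for (int c : cset) scan_antidiagonal(s, n, c, min_len, max_mm, best);
  }
  return best;
}

static List hit_to_list(const IRHit& h) {
  if (!h.valid) return List::create(Named("found") = false);
  return List::create(Named("found") = true,
                      Named("start1") = h.s1, Named("start2") = h.s2,
                      Named("length") = h.len, Named("mismatches") = h.mm);
}

// [[Rcpp::export(name = ".ir_detect_cpp")]]
List ir_detect_cpp(std::string seq, int min_len, int max_mismatch) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  IRHit best = detect_core(s, n, min_len, max_mismatch);
  return hit_to_list(best);
}

// Brute-force oracle: enumerate anchors (u = copy1 start, v = copy2 end,
// exclusive) on the circle, extend forward under the mismatch budget and the
// disjointness constraint, keep left-maximal windows only.
// [[Rcpp::export(name = ".ir_brute_cpp")]]
List ir_brute_cpp(std::string seq, int min_len, int max_mismatch) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  IRHit best;
  for (int u = 0; u < n; ++u) {
    for (int v = 0; v < n; ++v) {
      // pairing t: s[u+t] vs comp(s[v-1-t]); window length L covers
      // copy1=[u,u+L), copy2=[v-L,v) (mod n)
      int mm = 0, L = 0;
      while (true) {
        if (2 * (L + 1) > n) break;  // copies cannot exceed the circle
        // disjointness (abutting allowed): gap from copy1 end to copy2 start
        // plus gap from copy2 end to copy1 start must equal n - 2L
        int Lx = L + 1;
        int g1 = ((v - Lx - (u + Lx)) % n + 2 * n) % n;
        int g2 = ((u - v) % n + 2 * n) % n;
        if (g1 + g2 != n - 2 * Lx) break;
        int a = s[(u + L) % n];
        int b = s[((v - 1 - L) % n + n) % n];
        bool mat = (a < 4 && b < 4 && a == cmp4(b));
        if (!mat && mm == max_mismatch) break;
        if (!mat) ++mm;
        ++L;
      }
      if (L < min_len) continue;
      // left-maximality: extension to anchor (u-1, v+1) adds pair
      // (u-1, v); it must be infeasible
      bool feasible = true;
      int Lx = L + 1;
      if (2 * Lx > n) feasible = false;
      if (feasible) {
        int u2 = ((u - 1) % n + n) % n, v2 = (v + 1) % n;
        int g1 = ((v2 - Lx - (u2 + Lx)) % n + 2 * n) % n;
        int g2 = ((u2 - v2) % n + 2 * n) % n;
        if (g1 + g2 != n - 2 * Lx) feasible = false;
        if (feasible) {
          int a = s[u2];
          int b = s[v % n];
          bool mat = (a < 4 && b < 4 && a == cmp4(b));
          if (!mat && mm == max_mismatch) feasible = false;
        }
      }
      if (feasible) continue;  // not maximal
      int c = (int)(((long long)u + v - 1) % n);
      consider(best, u, u + L - 1, ((c % n) + n) % n, n, mm);
    }
  }
  return hit_to_list(best);
}
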