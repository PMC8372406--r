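// Repeat detectors: perfect SSR runs, dispersed repeats (Forward / Reverse /
// Complement / Palindromic, Hamming-budget maximal windows, seeded) plus a
// definition-driven brute-force oracle, and a simplified tandem-repeat
// scanner (period scan + majority consensus scoring, substitutions only).

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
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
static const char* BASES = "ACGTN";

// ---------------------------------------------------------------- SSR ------

static bool primitive_motif(const std::vector<int>& s, int start, int mlen,
                            int n) {
  for (int d = 1; d < mlen; ++d) {
    if (mlen % d != 0) continue;
    bool power = true;
    for (int t = d; t < mlen && power; ++t)
      if (s[(start + t) % n] != s[(start + t - d) % n]) power = false;
    if (power) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".ssr_scan_cpp")]]
DataFrame ssr_scan_cpp(std::string seq, IntegerVector thresholds,
                       bool circular) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  std::vector<std::string> motifs;
  std::vector<int> copies, starts, lens;
  int maxm = thresholds.size();
  for (int mlen = 1; mlen <= maxm; ++mlen) {
    int thr = thresholds[mlen - 1];
    if (thr <= 0 || n <= mlen) continue;
    int span = circular ? n : n - mlen;     // eq defined on [0, span)
    std::vector<char> eq(span, 0);
    bool all_true = true;
    for (int x = 0; x < span; ++x) {
      int a = s[x], b = s[(x + mlen) % n];
      eq[x] = (a < 4 && a == b);
      if (!eq[x]) all_true = false;
    }
    if (circular && all_true) {
      // fully periodic circle: one run covering everything
      if (n / mlen >= thr && primitive_motif(s, 0, mlen, n)) {
        motifs.push_back(seq.substr(0, mlen));
        copies.push_back(n / mlen); starts.push_back(0); lens.push_back(n);
      }
      continue;
    }
    // maximal runs of eq; on a circle a run may wrap: start after a false
    int scan_from = 0;
    if (circular) {
      while (scan_from < span && eq[scan_from]) ++scan_from;
      if (scan_from == span) continue;
    }
    long long x = scan_from, seen = 0;
    while (seen < span) {
      while (seen < span && !eq[x % span]) { ++x; ++seen; }
      if (seen >= span) break;
      int x0 = (int)(x % span);
      int t = 0;
      while (seen < span && eq[x % span]) { ++x; ++seen; ++t; }
      int total = t + mlen;
      if (total > n) total = n;
      int cp = total / mlen;
      if (cp >= thr && primitive_motif(s, x0, mlen, n)) {
        std::string m;
        for (int q = 0; q < mlen; ++q) m.push_back(BASES[s[(x0 + q) % n]]);
        motifs.push_back(m); copies.push_back(cp);
        starts.push_back(x0); lens.push_back(total);
      }
    }
  }
  return DataFrame::create(Named("motif") = motifs, Named("copies") = copies,
                           Named("start") = starts, Named("length") = lens,
                           Named("stringsAsFactors") = false);
}

// ----------------------------------------------------------- dispersed -----

// kinds: 0 Forward, 1 Reverse, 2 Complement, 3 Palindromic
// Forward/Complement pair (x, x+d) on diagonal d >= 1;
// Reverse/Palindromic pair (x, c-x) on anti-diagonal c with x < c-x.
struct DHit { int kind, i, j, len, mm; };

static inline bool dpair_match(const std::vector<int>& s, int kind, int x,
                               int y) {
  int a = s[x], b = s[y];
  if (a >= 4 || b >= 4) return false;
  if (kind == 0 || kind == 1) return a == b;       // Forward / Reverse
  return a == cmp4(b);                              // Complement / Palindromic
}

static inline void line_domain(int kind, bool anti, long long key, int n,
                               int& lo, int& hi) {
  (void)kind;
  if (!anti) { lo = 0; hi = n - 1 - (int)key; }
  else {
    lo = (int)std::max(0LL, key - (n - 1));
    hi = (int)((key - 1) / 2);       // x < c - x
  }
}

static void dedupe(std::vector<DHit>& hits) {
  std::sort(hits.begin(), hits.end(), [](const DHit& a, const DHit& b) {
    if (a.kind != b.kind) return a.kind < b.kind;
    if (a.len != b.len) return a.len > b.len;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  hits.erase(std::unique(hits.begin(), hits.end(),
                         [](const DHit& a, const DHit& b) {
                           return a.kind == b.kind && a.i == b.i &&
                                  a.j == b.j && a.len == b.len;
                         }),
             hits.end());
  std::vector<DHit> keep;
  for (const DHit& h : hits) {
    bool nested = false;
    for (const DHit& g : keep) {
      if (g.kind != h.kind || g.len <= h.len) continue;
      if (h.i >= g.i && h.i + h.len <= g.i + g.len && h.j >= g.j &&
          h.j + h.len <= g.j + g.len) { nested = true; break; }
    }
    if (!nested) keep.push_back(h);
  }
  hits.swap(keep);
}

static DataFrame dhits_to_df(std::vector<DHit>& hits) {
  dedupe(hits);
  std::sort(hits.begin(), hits.end(), [](const DHit& a, const DHit& b) {
    if (a.kind != b.kind) return a.kind < b.kind;
    if (a.i != b.i) return a.i < b.i;
    if (a.j != b.j) return a.j < b.j;
    return a.len > b.len;
  });
  int H = (int)hits.size();
  CharacterVector kind(H);
  IntegerVector i1(H), i2(H), len(H), mm(H);
  const char* KN[4] = {"Forward", "Reverse", "Complement", "Palindromic"};
  for (int t = 0; t < H; ++t) {
    kind[t] = KN[hits[t].kind]; i1[t] = hits[t].i; i2[t] = hits[t].j;
    len[t] = hits[t].len; mm[t] = hits[t].mm;
  }
  return DataFrame::create(Named("kind") = kind, Named("start1") = i1,
                           Named("start2") = i2, Named("length") = len,
                           Named("mismatches") = mm,
                           Named("stringsAsFactors") = false);
}

// emit one maximal window [ws, we] on a line
static inline void push_window(std::vector<DHit>& out, int kind, bool anti,
                               long long key, int ws, int we, int mm,
                               int min_len) {
  int L = we - ws + 1;
  if (L < min_len) return;
  DHit h;
  h.kind = kind; h.len = L; h.mm = mm; h.i = ws;
  h.j = anti ? (int)(key - we) : ws + (int)key;
  out.push_back(h);
}

struct SeedExtender {
  const std::vector<int>& s;
  int n, max_mm, min_len;
  std::vector<DHit>& out;
  // scanned extents per line, merged on growth
  std::unordered_map<long long, std::vector<std::pair<int, int>>> cover;

  SeedExtender(const std::vector<int>& s_, int n_, int max_mm_, int min_len_,
               std::vector<DHit>& out_)
      : s(s_), n(n_), max_mm(max_mm_), min_len(min_len_), out(out_) {}

  void process(int kind, bool anti, long long key, int rs, int re) {
    int lo, hi;
    line_domain(kind, anti, key, n, lo, hi);
    if (anti) {
      // normalize a seed run sitting on the upper mirror half, clamp to domain
      int rs2 = (int)(key - re), re2 = (int)(key - rs);
      if (rs2 < rs) { rs = rs2; re = re2; }
      if (rs < lo) rs = lo;
      if (re > hi) re = hi;
      if (rs > re) return;
    }
    if (hi - lo + 1 < min_len) return;
    long long id = (long long)kind * (4LL * n + 4) + key;
    auto& cv = cover[id];
    for (auto& iv : cv)
      if (rs >= iv.first && re <= iv.second) return;
    // walk left and right from the seed run collecting mismatch positions
    std::vector<int> Lmm, Rmm;
    int x = rs - 1;
    while ((int)Lmm.size() < max_mm + 1 && x >= lo) {
      int y = anti ? (int)(key - x) : x + (int)key;
      if (!dpair_match(s, kind, x, y)) Lmm.push_back(x);
      --x;
    }
    int scanL = x + 1;
    x = re + 1;
    while ((int)Rmm.size() < max_mm + 1 && x <= hi) {
      int y = anti ? (int)(key - x) : x + (int)key;
      if (!dpair_match(s, kind, x, y)) Rmm.push_back(x);
      ++x;
    }
    int scanR = x - 1;
    cv.push_back(std::make_pair(scanL, scanR));
    if (cv.size() > 16) {  // merge to keep containment checks cheap
      std::sort(cv.begin(), cv.end());
      std::vector<std::pair<int, int>> merged;
      for (auto& iv : cv) {
        if (!merged.empty() && iv.first <= merged.back().second + 1) {
          if (iv.second > merged.back().second) merged.back().second = iv.second;
        } else merged.push_back(iv);
      }
      cv.swap(merged);
    }
    int nL = (int)Lmm.size(), nR = (int)Rmm.size();
    if (nL + nR <= max_mm) {
      push_window(out, kind, anti, key, lo, hi, nL + nR, min_len);
      return;
    }
    int aLo = std::max(0, max_mm - nR), aHi = std::min(max_mm, nL);
    for (int a = aLo; a <= aHi; ++a) {
      int b = max_mm - a;
      int left = (a < nL) ? Lmm[a] : lo - 1;
      int right = (b < nR) ? Rmm[b] : hi + 1;
      push_window(out, kind, anti, key, left + 1, right - 1, a + b, min_len);
    }
  }
};

static DataFrame dispersed_full(const std::vector<int>& s, int n, int min_len,
                                int max_mm);

// [[Rcpp::export(name = ".dispersed_scan_cpp")]]
DataFrame dispersed_scan_cpp(std::string seq, int min_len, int max_mm) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  int k = (min_len - max_mm) / (max_mm + 1);
  if (k > 12) k = 12;
  if (k < 4 || n < 2 * k) return dispersed_full(s, n, min_len, max_mm);

  std::vector<DHit> out;
  std::unordered_map<uint64_t, std::vector<int>> idx;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  {
    uint64_t v = 0; int run = 0;
    for (int q = 0; q < n; ++q) {
      int b = s[q];
      if (b >= 4) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx[v].push_back(q - k + 1);
    }
  }
  SeedExtender ext(s, n, max_mm, min_len, out);
  uint64_t fwd = 0, rcv = 0, rev = 0, cmv = 0;
  int run = 0;
  for (int q = 0; q < n; ++q) {
    int b = s[q];
    if (b >= 4) { run = 0; fwd = rcv = rev = cmv = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    cmv = ((cmv << 2) | (uint64_t)cmp4(b)) & mask;
    rev = (rev >> 2) | ((uint64_t)b << (2 * (k - 1)));
    rcv = (rcv >> 2) | ((uint64_t)cmp4(b) << (2 * (k - 1)));
    if (++run < k) continue;
    int i = q - k + 1;
    auto itf = idx.find(fwd);
    if (itf != idx.end())
      for (int q2 : itf->second)
        if (q2 != i)
          ext.process(0, false, std::abs(q2 - i), std::min(i, q2),
                      std::min(i, q2) + k - 1);
    auto itc = idx.find(cmv);
    if (itc != idx.end())
      for (int q2 : itc->second)
        if (q2 != i)
          ext.process(2, false, std::abs(q2 - i), std::min(i, q2),
                      std::min(i, q2) + k - 1);
    auto itr = idx.find(rev);
    if (itr != idx.end())
      for (int q2 : itr->second)
        ext.process(1, true, (long long)i + q2 + k - 1, i, i + k - 1);
    auto itp = idx.find(rcv);
    if (itp != idx.end())
      for (int q2 : itp->second)
        ext.process(3, true, (long long)i + q2 + k - 1, i, i + k - 1);
  }
  return dhits_to_df(out);
}

// Definition-driven enumeration over every anchor; shared by the brute oracle
// and by the small-parameter fallback of the main detector.
static void enumerate_anchors(const std::vector<int>& s, int n, int min_len,
                              int max_mm, std::vector<DHit>& out) {
  for (int kind = 0; kind < 4; ++kind) {
    bool anti = (kind == 1 || kind == 3);
    if (!anti) {
      for (int d = 1; d < n; ++d) {
        for (int i = 0; i + d < n; ++i) {
          int mm = 0, L = 0;
          while (i + L + d < n) {
            bool mat = dpair_match(s, kind, i + L, i + L + d);
            if (!mat && mm == max_mm) break;
            if (!mat) ++mm;
            ++L;
          }
          if (L < min_len) continue;
          if (i - 1 >= 0) {  // left-maximality
            bool mat = dpair_match(s, kind, i - 1, i - 1 + d);
            if (mat || mm < max_mm) continue;
          }
          DHit h; h.kind = kind; h.i = i; h.j = i + d; h.len = L; h.mm = mm;
          out.push_back(h);
        }
      }
    } else {
      for (long long c = 1; c <= 2LL * n - 3; ++c) {
        int lo, hi;
        line_domain(kind, true, c, n, lo, hi);
        for (int x = lo; x <= hi; ++x) {
          int mm = 0, L = 0;
          while (x + L <= hi) {
            bool mat = dpair_match(s, kind, x + L, (int)c - (x + L));
            if (!mat && mm == max_mm) break;
            if (!mat) ++mm;
            ++L;
          }
          if (L < min_len) continue;
          if (x - 1 >= lo) {
            bool mat = dpair_match(s, kind, x - 1, (int)c - (x - 1));
            if (mat || mm < max_mm) continue;
          }
          DHit h; h.kind = kind; h.i = x; h.j = (int)c - (x + L - 1);
          h.len = L; h.mm = mm;
          out.push_back(h);
        }
      }
    }
  }
}

static DataFrame dispersed_full(const std::vector<int>& s, int n, int min_len,
                                int max_mm) {
  std::vector<DHit> out;
  enumerate_anchors(s, n, min_len, max_mm, out);
  return dhits_to_df(out);
}

// [[Rcpp::export(name = ".dispersed_brute_cpp")]]
DataFrame dispersed_brute_cpp(std::string seq, int min_len, int max_mm) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  return dispersed_full(s, n, min_len, max_mm);
}

// -------------------------------------------------------------- tandem -----

// [[Rcpp::export(name = ".tandem_scan_cpp")]]
DataFrame tandem_scan_cpp(std::string seq, int match_w, int mismatch_w,
                          int indel_w, int min_score, int max_period,
                          double min_copies) {
  (void)indel_w;  // substitution-only scanner; indels split arrays (documented)
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  std::vector<int> P, ST, LN, SC;
  std::vector<double> CN;
  std::vector<std::string> CONS;
  int pmax = std::min(max_period, n / 2);
  const int maxgap = 3;  // merge eq-runs separated by <= this many misses
  for (int p = 1; p <= pmax; ++p) {
    int span = n - p;
    int x = 0;
    while (x < span) {
      if (!(s[x] < 4 && s[x] == s[x + p])) { ++x; continue; }
      int a = x, b = x, gap = 0, last_true = x;
      while (b + 1 < span) {
        ++b;
        if (s[b] < 4 && s[b] == s[b + p]) { last_true = b; gap = 0; }
        else if (++gap > maxgap) break;
      }
      b = last_true;
      x = b + 2;
      int T = b - a + 1 + p;
      if (T < (int)std::ceil(min_copies * p)) continue;
      std::string cons(p, 'N');  // per-phase majority consensus
      for (int col = 0; col < p; ++col) {
        int cnt[4] = {0, 0, 0, 0};
        for (int pos = a + col; pos < a + T; pos += p)
          if (s[pos] < 4) cnt[s[pos]]++;
        int bi = 0;
        for (int z = 1; z < 4; ++z)
          if (cnt[z] > cnt[bi]) bi = z;
        cons[col] = BASES[bi];
      }
      long M = 0, X = 0;
      for (int pos = a; pos < a + T; ++pos) {
        int cb = enc(cons[(pos - a) % p]);
        if (s[pos] < 4 && s[pos] == cb) ++M; else ++X;
      }
      // one perfect unit carries no credit: subtract match_w * period
      long score = (long)match_w * M - (long)mismatch_w * X -
                   (long)match_w * p;
      if (score >= min_score) {
        P.push_back(p); ST.push_back(a); LN.push_back(T);
        SC.push_back((int)score); CN.push_back((double)T / p);
        CONS.push_back(cons);
      }
    }
  }
  // suppress the same array re-reported at a multiple of the period
  std::vector<bool> drop(P.size(), false);
  for (size_t i = 0; i < P.size(); ++i) {
    for (size_t j = 0; j < P.size(); ++j) {
      if (i == j || drop[i] || drop[j]) continue;
      if (P[j] >= P[i] || P[i] % P[j] != 0) continue;
      int o1 = std::max(ST[i], ST[j]);
      int o2 = std::min(ST[i] + LN[i], ST[j] + LN[j]);
      if (o2 - o1 >= (int)(0.8 * LN[i])) drop[i] = true;
    }
  }
  std::vector<int> P2, ST2, LN2, SC2;
  std::vector<double> CN2;
  std::vector<std::string> CONS2;
  for (size_t i = 0; i < P.size(); ++i) {
    if (drop[i]) continue;
    P2.push_back(P[i]); ST2.push_back(ST[i]); LN2.push_back(LN[i]);
    SC2.push_back(SC[i]); CN2.push_back(CN[i]); CONS2.push_back(CONS[i]);
  }
  return DataFrame::create(
      Named("period") = P2, Named("start") = ST2, Named("length") = LN2,
      Named("copy_number") = CN2, Named("score") = SC2,
      Named("consensus") = CONS2, Named("stringsAsFactors") = false);
}
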