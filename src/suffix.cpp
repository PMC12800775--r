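#include <Rcpp.h>
using namespace Rcpp;

static inline int base_code2(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 3; case 'T': return 4;
    default: return -1;
  }
}

// Suffix array of S + sentinel via prefix doubling (O(n log^2 n), worst-case
// safe, no recursion). The sentinel sorts before every base, so sa[0] = n-1.
// Returns 0-based positions.
// [[Rcpp::export]]
IntegerVector cpp_suffix_array(std::string s) {
  int n = (int)s.size() + 1;
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n - 1; ++i) {
    int c = base_code2(s[i]);
    if (c < 0) stop("non-ACGT character in superstring");
    rnk[i] = c;
  }
  rnk[n - 1] = 0;
  for (int i = 0; i < n; ++i) sa[i] = i;
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + len < n ? rnk[a + len] : -1;
      int rb = b + len < n ? rnk[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return wrap(sa);
}

// BWT codes of S + sentinel given its suffix array: sprime[i] = text[sa[i]-1 mod n].
// [[Rcpp::export]]
IntegerVector cpp_bwt_codes(std::string s, IntegerVector sa) {
  int n = (int)s.size() + 1;
  if (sa.size() != n) stop("suffix array length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int p = (sa[i] + n - 1) % n;
    out[i] = (p == n - 1) ? 0 : base_code2(s[p]);
  }
  return out;
}

// Adjacent LCP values by Kasai's algorithm over S + sentinel:
// out[i] = LCP(suffix sa[i], suffix sa[i+1]) for i < n-1, out[n-1] = 0.
// [[Rcpp::export]]
IntegerVector cpp_lcp_adjacent(std::string s, IntegerVector sa) {
  int n = (int)s.size() + 1;
  if (sa.size() != n) stop("suffix array length mismatch");
  std::vector<int> isa(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) isa[sa[i]] = i;
  std::string t = s + '\0';  // sentinel strictly smaller than any base
  int h = 0;
  for (int p = 0; p < n; ++p) {
    if (isa[p] == n - 1) { h = 0; continue; }
    int q = sa[isa[p] + 1];
    while (p + h < n - 1 && q + h < n - 1 && t[p + h] == t[q + h]) ++h;
    lcp[isa[p]] = h;
    if (h > 0) --h;
  }
  return wrap(lcp);
}

// LF-mapping inversion of a BWT image (codes 0..4, exactly one sentinel 0):
// recovers the original text (without sentinel) and, alongside, the SA-rank
// visited when each text position was emitted, from which the caller can read
// the SA-transformed mask back into text order.
// [[Rcpp::export]]
List cpp_bwt_invert(IntegerVector sprime) {
  int n = sprime.size();
  int nsent = 0;
  for (int i = 0; i < n; ++i) {
    if (sprime[i] < 0 || sprime[i] > 4) stop("invalid BWT code");
    if (sprime[i] == 0) ++nsent;
  }
  if (nsent != 1) stop("malformed MBWT image: expected exactly one sentinel");
  std::vector<int> C(6, 0);
  for (int i = 0; i < n; ++i) C[sprime[i] + 1]++;
  for (int c = 1; c < 6; ++c) C[c] += C[c - 1];
  // occ on the fly via per-row LF precomputation
  std::vector<int> lf(n), cnt(5, 0);
  for (int i = 0; i < n; ++i) {
    int c = sprime[i];
    lf[i] = C[c] + cnt[c];
    cnt[c]++;
  }
  static const char bases[] = "$ACGT";
  std::string text(n - 1, 'N');
  IntegerVector rank_at(n - 1);  // SA-rank of the suffix starting at position t
  int i = 0;
  for (int t = n - 2; t >= 0; --t) {
    text[t] = bases[sprime[i]];
    i = lf[i];
    rank_at[t] = i;
  }
  return List::create(_["text"] = text, _["rank_at"] = rank_at);
}
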