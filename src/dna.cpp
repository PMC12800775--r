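#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// 2-bit-style base codes with a separate sentinel: $=0 < A=1 < C=2 < G=3 < T=4.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 3; case 'T': return 4;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    default: return 0;
  }
}

std::string rc_string(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    char x = comp_base(c);
    if (x == 0) stop("non-ACGT character in DNA string");
    c = x;
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    out[i] = rc_string(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r = rc_string(s);
    out[i] = (r < s) ? r : s;
  }
  return out;
}

// All k-length windows over ACGT of all sequences, optionally canonicalized;
// windows touching a non-ACGT letter are skipped. Returns the sorted unique set.
// [[Rcpp::export]]
CharacterVector cpp_extract_kmers(CharacterVector seqs, int k, bool canonical) {
  std::unordered_set<std::string> seen;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    R_xlen_t n = (R_xlen_t)s.size();
    if (n < k) continue;
    R_xlen_t valid = 0;  // length of current run of ACGT letters ending here
    for (R_xlen_t i = 0; i < n; ++i) {
      valid = (base_code(s[i]) < 0) ? 0 : valid + 1;
      if (valid >= k) {
        std::string w = s.substr(i - k + 1, k);
        if (canonical) {
          std::string r = rc_string(w);
          if (r < w) w = r;
        }
        seen.insert(w);
      }
    }
  }
  std::vector<std::string> v(seen.begin(), seen.end());
  std::sort(v.begin(), v.end());
  return wrap(v);
}

// Recompute a mask over S for a given represented set (sorted unique k-mers,
// canonical under the bidirectional model). min-one marks the leftmost
// occurrence of each represented k-mer; max-one marks every occurrence.
// [[Rcpp::export]]
LogicalVector cpp_mask_policy(std::string S, CharacterVector kmers, int k,
                              bool bidir, bool minone) {
  std::unordered_set<std::string> K;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) K.insert(as<std::string>(kmers[i]));
  R_xlen_t n = (R_xlen_t)S.size();
  LogicalVector M(n);
  std::unordered_set<std::string> marked;
  for (R_xlen_t p = 0; p + k <= n; ++p) {
    std::string w = S.substr(p, k);
    if (bidir) {
      std::string r = rc_string(w);
      if (r < w) w = r;
    }
    if (K.count(w)) {
      if (minone) {
        if (!marked.count(w)) { M[p] = true; marked.insert(w); }
      } else {
        M[p] = true;
      }
    }
  }
  return M;
}

// The set of k-mers (canonicalized per model) with >= 1 mask-1 occurrence.
// [[Rcpp::export]]
CharacterVector cpp_represented(std::string S, LogicalVector M, int k, bool bidir) {
  std::unordered_set<std::string> K;
  R_xlen_t n = (R_xlen_t)S.size();
  for (R_xlen_t p = 0; p + k <= n; ++p) {
    if (!M[p]) continue;
    std::string w = S.substr(p, k);
    if (bidir) {
      std::string r = rc_string(w);
      if (r < w) w = r;
    }
    K.insert(w);
  }
  std::vector<std::string> v(K.begin(), K.end());
  std::sort(v.begin(), v.end());
  return wrap(v);
}
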