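#include <Rcpp.h>
#include <deque>
#include <map>
#include <set>
using namespace Rcpp;

// Global greedy shortest-superstring heuristic over a k-mer set.
//
// Strings are merged in order of decreasing suffix-prefix overlap length
// (k-1 down to 1); at a fixed overlap length candidate merges are processed
// in lexicographic order of (left oriented string, right oriented string,
// orientation flags, insertion id), which makes the construction fully
// deterministic. Under the bidirectional model every chain is usable in
// either orientation; a merge fixes the relative orientation of the two
// chains and consumes both orientations of the absorbed chain, so each
// canonical k-mer is placed exactly once. Self-merges (which would close a
// cycle) are forbidden. Chains left over after overlap length 1 are
// concatenated in lexicographic order of their canonical orientation.

static inline char cbase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  }
  return 0;
}

namespace {

struct Chain {
  // Logical string = flip ? reverse-complement(d) : d. The deque plus flip
  // flag makes both orientation flips and logical-end appends cheap.
  std::deque<char> d;
  bool flip = false;
  bool alive = true;
  size_t len() const { return d.size(); }
  char lat(size_t t) const { return flip ? cbase(d[d.size() - 1 - t]) : d[t]; }
};

struct Entry { int id; bool o; };  // chain id used in orientation o (o=1: RC)

static inline char oat(const Chain& c, bool o, size_t t) {
  return o ? cbase(c.lat(c.len() - 1 - t)) : c.lat(t);
}

struct OrientCmp {
  const std::vector<Chain>* ch;
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.id == b.id && a.o == b.o) return false;  // self-compare on erase-by-value
    const Chain& A = (*ch)[a.id];
    const Chain& B = (*ch)[b.id];
    size_t la = A.len(), lb = B.len(), m = la < lb ? la : lb;
    for (size_t t = 0; t < m; ++t) {
      char x = oat(A, a.o, t), y = oat(B, b.o, t);
      if (x != y) return x < y;
    }
    if (la != lb) return la < lb;
    if (a.o != b.o) return !a.o;
    return a.id < b.id;
  }
};

static std::string okey(const Chain& c, bool o, size_t l, bool prefix) {
  std::string s(l, 0);
  size_t n = c.len();
  for (size_t t = 0; t < l; ++t) s[t] = oat(c, o, prefix ? t : n - l + t);
  return s;
}

}  // namespace

// [[Rcpp::export]]
std::string cpp_greedy_superstring(CharacterVector kmers, int k, bool bidir) {
  int m = kmers.size();
  std::vector<Chain> chains(m);
  for (int i = 0; i < m; ++i) {
    std::string s = as<std::string>(kmers[i]);
    chains[i].d.assign(s.begin(), s.end());
  }
  OrientCmp cmp{&chains};
  int n_orient = bidir ? 2 : 1;

  for (int l = k - 1; l >= 1; --l) {
    std::map<std::string, std::set<Entry, OrientCmp>> heads;
    std::set<Entry, OrientCmp> work(cmp);
    for (int i = 0; i < m; ++i) {
      if (!chains[i].alive) continue;
      for (int o = 0; o < n_orient; ++o) {
        Entry e{i, o == 1};
        auto it = heads.find(okey(chains[i], e.o, l, true));
        if (it == heads.end())
          it = heads.emplace(okey(chains[i], e.o, l, true),
                             std::set<Entry, OrientCmp>(cmp)).first;
        it->second.insert(e);
        work.insert(e);
      }
    }
    while (!work.empty()) {
      Entry L = *work.begin();
      work.erase(work.begin());
      if (!chains[L.id].alive) continue;
      std::string key = okey(chains[L.id], L.o, l, false);
      auto hit = heads.find(key);
      if (hit == heads.end()) continue;
      const Entry* best = nullptr;
      for (const Entry& e : hit->second) {
        if (e.id != L.id && chains[e.id].alive) { best = &e; break; }
      }
      if (!best) continue;
      Entry R = *best;

      // Drop all stale references to both chains before mutating them.
      for (int o = 0; o < n_orient; ++o) {
        for (int id : {L.id, R.id}) {
          Entry e{id, o == 1};
          work.erase(e);
          auto it = heads.find(okey(chains[id], e.o, l, true));
          if (it != heads.end()) it->second.erase(e);
        }
      }

      // Merge the smaller chain into the larger so the surviving deque is
      // never copied; chain growth by single k-mers then costs O(k) a step.
      Chain& A = chains[L.id];
      Chain& B = chains[R.id];
      int survivor;
      if (A.len() >= B.len()) {
        if (L.o) A.flip = !A.flip;  // logical A := oriented left string
        size_t lb = B.len();
        for (size_t t = (size_t)l; t < lb; ++t) {
          char ch = oat(B, R.o, t);
          if (A.flip) A.d.push_front(cbase(ch)); else A.d.push_back(ch);
        }
        B.alive = false;
        B.d.clear();
        survivor = L.id;
      } else {
        if (R.o) B.flip = !B.flip;  // logical B := oriented right string
        size_t la = A.len();
        for (size_t t = la - (size_t)l; t-- > 0;) {
          char ch = oat(A, L.o, t);  // prepend left part, right to left
          if (B.flip) B.d.push_back(cbase(ch)); else B.d.push_front(ch);
        }
        A.alive = false;
        A.d.clear();
        survivor = R.id;
      }

      for (int o = 0; o < n_orient; ++o) {
        Entry e{survivor, o == 1};
        Chain& S = chains[survivor];
        auto it = heads.find(okey(S, e.o, l, true));
        if (it == heads.end())
          it = heads.emplace(okey(S, e.o, l, true),
                             std::set<Entry, OrientCmp>(cmp)).first;
        it->second.insert(e);
        work.insert(e);
      }
    }
  }

  std::vector<std::string> parts;
  for (int i = 0; i < m; ++i) {
    if (!chains[i].alive) continue;
    std::string s(chains[i].len(), 0);
    for (size_t t = 0; t < s.size(); ++t) s[t] = chains[i].lat(t);
    if (bidir) {
      std::string r(s.size(), 0);
      for (size_t t = 0; t < s.size(); ++t) r[t] = cbase(s[s.size() - 1 - t]);
      if (r < s) s = r;
    }
    parts.push_back(s);
  }
  std::sort(parts.begin(), parts.end());
  std::string S;
  for (const std::string& p : parts) S += p;
  return S;
}
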