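#include <Rcpp.h>
using namespace Rcpp;

// FM-index query engine over an MBWT image. The image is passed as plain
// vectors (BWT codes 0..4 with 0 = sentinel, SA-transformed mask bits); full
// cumulative occurrence tables are (re)built per batch call in O(n) -- rank
// is then O(1) per step. Physical succinctness is accounted analytically
// elsewhere; here the contract is functional.

static inline int qcode(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 3; case 'T': return 4;
    default: return -1;
  }
}
static inline char qcomp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  }
  return 0;
}

namespace {

struct FM {
  int n;
  std::vector<int> code;            // BWT codes
  std::vector<int> C;               // C[c] = # characters with code < c; C[5] = n
  std::vector<std::array<int, 5>> occ;  // occ[i][c] = # c among code[0..i-1]
  std::vector<int> m1;              // m1[i] = # mask-1 bits among mprime[0..i-1]
  std::vector<int> mask;

  void build(const IntegerVector& sprime, const IntegerVector& mprime) {
    n = sprime.size();
    code.assign(sprime.begin(), sprime.end());
    mask.assign(mprime.begin(), mprime.end());
    C.assign(6, 0);
    occ.assign(n + 1, {0, 0, 0, 0, 0});
    m1.assign(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      occ[i + 1] = occ[i];
      occ[i + 1][code[i]]++;
      m1[i + 1] = m1[i] + (mask[i] ? 1 : 0);
      C[code[i] + 1]++;
    }
    for (int c = 1; c < 6; ++c) C[c] += C[c - 1];
  }

  inline int rank(int c, int i) const { return occ[i][c]; }
  inline int rank1m(int i) const { return m1[i]; }

  inline void step(int c, int& i, int& j) const {
    i = C[c] + rank(c, i);
    j = C[c] + rank(c, j);
  }

  // Backward search with early exit; [0, n) start, empty interval = (0, 0).
  void search(const char* q, int k, int& i, int& j) const {
    i = 0; j = n;
    for (int t = k - 1; t >= 0; --t) {
      int c = qcode(q[t]);
      if (c < 0) { i = 0; j = 0; return; }
      step(c, i, j);
      if (i == j) { i = 0; j = 0; return; }
    }
  }
};

enum Op { OP_MEMBER = 0, OP_GENERAL = 1, OP_LOOKUP = 2 };

// Answer for a non-empty SA interval; -2 = "no marked occurrence here".
static inline int interval_answer(const FM& fm, Op op, int i, int j) {
  switch (op) {
    case OP_MEMBER:  return fm.mask[i] ? 1 : -2;
    case OP_GENERAL: return fm.rank1m(j) > fm.rank1m(i) ? 1 : -2;
    case OP_LOOKUP: {
      int ri = fm.rank1m(i), rj = fm.rank1m(j);
      return ri < rj ? ri : -2;
    }
  }
  return -2;
}

static inline int negative_answer(Op op) { return op == OP_LOOKUP ? -1 : 0; }

static inline void bump(int& counter, bool forward, int sat) {
  counter += forward ? 1 : -1;
  if (counter > sat) counter = sat;
  if (counter < -sat) counter = -sat;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_backward_search(IntegerVector sprime, IntegerVector mprime,
                                  std::string q) {
  FM fm;
  fm.build(sprime, mprime);
  int i, j;
  fm.search(q.c_str(), (int)q.size(), i, j);
  if (q.size() == 0) { i = 0; j = fm.n; }
  return IntegerVector::create(i, j);
}

// Batch isolated queries. op: 0 = Member (max-one), 1 = Member with a general
// mask, 2 = Lookup (min-one). Under the bidirectional model the strand
// suggested by the saturating counter is searched first and the other strand
// is tried whenever the first yields no marked occurrence; the counter moves
// +1 on a forward hit, -1 on a reverse-complement hit, saturating at +/-sat.
// [[Rcpp::export]]
List cpp_query_batch(IntegerVector sprime, IntegerVector mprime,
                     CharacterVector queries, int k, bool bidir, int op,
                     int counter0, int sat) {
  FM fm;
  fm.build(sprime, mprime);
  int counter = counter0;
  IntegerVector ans(queries.size());
  std::string rcbuf(k, 'A');
  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    if ((int)q.size() != k) stop("query length must equal k");
    int result = negative_answer((Op)op);
    int nstrand = bidir ? 2 : 1;
    bool first_fwd = !bidir || counter >= 0;
    for (int s = 0; s < nstrand; ++s) {
      bool fwd = (s == 0) ? first_fwd : !first_fwd;
      const char* qp;
      if (fwd) {
        qp = q.c_str();
      } else {
        for (int t = 0; t < k; ++t) rcbuf[t] = qcomp(q[k - 1 - t]);
        qp = rcbuf.c_str();
      }
      int i, j;
      fm.search(qp, k, i, j);
      if (i == j) continue;
      int a = interval_answer(fm, (Op)op, i, j);
      if (a != -2) {
        result = a;
        if (bidir) bump(counter, fwd, sat);
        break;
      }
    }
    ans[qi] = result;
  }
  return List::create(_["answers"] = ans, _["counter"] = counter);
}

// Batch Access: h -> k-mer, via select on the mask and the psi-walk
// (F-column character, then select on the BWT) for k steps.
// [[Rcpp::export]]
CharacterVector cpp_access_batch(IntegerVector sprime, IntegerVector mprime,
                                 IntegerVector hs, int k) {
  FM fm;
  fm.build(sprime, mprime);
  std::vector<int> pos1;
  std::vector<std::vector<int>> selc(5);
  for (int i = 0; i < fm.n; ++i) {
    if (fm.mask[i]) pos1.push_back(i);
    selc[fm.code[i]].push_back(i);
  }
  static const char bases[] = "$ACGT";
  CharacterVector out(hs.size());
  for (R_xlen_t t = 0; t < hs.size(); ++t) {
    int h = hs[t];
    if (h < 0 || h >= (int)pos1.size())
      stop("hash %d out of range [0, %d)", h, (int)pos1.size());
    int i = pos1[h];
    std::string q(k, 'N');
    for (int step = 0; step < k; ++step) {
      int c = 4;
      while (c > 0 && fm.C[c] > i) --c;  // F-column character at row i
      if (c == 0) stop("Access walked into the sentinel; is the mask valid for k?");
      q[step] = bases[c];
      i = selc[c][i - fm.C[c]];
    }
    out[t] = q;
  }
  return out;
}

// Streamed queries over all k-mer starts of T.
//
// Within a strand pass the text is traversed in backward-search order (right
// to left on the forward strand, left to right on the reverse strand): after
// a k-mer found in S, the next one costs one kLCP range extension (linear
// scans to the flanking 0 bits) plus one backward-search step; a k-mer absent
// from S breaks the chain and the next position pays a full backward search.
// Under the bidirectional model T is split into blocks; each block is first
// queried entirely on the strand predicted by the saturating counter, and
// only the positions it left unanswered are retried on the other strand
// (chained where adjacent). Windows with non-ACGT letters answer negatively
// and reset the chain. Telemetry counts full backward searches, kLCP
// extensions, blocks, and retried positions.
// [[Rcpp::export]]
List cpp_stream_query(IntegerVector sprime, IntegerVector mprime,
                      LogicalVector klcp, std::string T, int k, bool bidir,
                      int op, int block_size, int counter0, int sat) {
  FM fm;
  fm.build(sprime, mprime);
  std::vector<int> kl(klcp.begin(), klcp.end());
  if ((int)kl.size() != fm.n) stop("kLCP length must match the image");
  int tn = (int)T.size();
  int tmax = tn - k;  // last k-mer start (0-based); negative => empty result
  int full = 0, ext = 0, nblocks = 0, retried = 0;
  int counter = counter0;
  if (tmax < 0) {
    return List::create(_["answers"] = IntegerVector(0),
                        _["full_searches"] = 0, _["extensions"] = 0,
                        _["blocks"] = 0, _["retried"] = 0,
                        _["counter"] = counter);
  }
  IntegerVector ans(tmax + 1);
  std::vector<char> valid(tmax + 1, 1);
  {
    int run = 0;
    for (int i = 0; i < tn; ++i) {
      run = (qcode(T[i]) < 0) ? 0 : run + 1;
      if (i >= k - 1) valid[i - k + 1] = run >= k;
    }
  }

  auto extend = [&](int& i, int& j) {
    while (i > 0 && kl[i - 1]) --i;
    while (j < fm.n && kl[j - 1]) ++j;
    ++ext;
  };

  // One chained pass over positions [lo, hi] on a fixed strand.
  // fwd strand: descending; reverse strand: ascending. Answers only
  // positions with pending[p] != 0; records found-in-S in had[].
  std::vector<char> pending(tmax + 1, 1);
  auto pass = [&](int lo, int hi, bool fwd, bool retry_pass) {
    int i = 0, j = 0;
    bool have = false;
    int from = fwd ? hi : lo, to = fwd ? lo : hi, dstep = fwd ? -1 : 1;
    int prev_p = -2;
    std::string buf(k, 'A');
    for (int p = from; fwd ? p >= to : p <= to; p += dstep) {
      if (!pending[p]) { continue; }
      if (!valid[p]) {
        ans[p] = negative_answer((Op)op);
        pending[p] = 0;
        have = false;
        prev_p = p;
        continue;
      }
      bool adjacent = (prev_p == p - dstep);
      if (have && adjacent) {
        extend(i, j);
        int c = fwd ? qcode(T[p]) : qcode(T[p + k - 1]);
        if (!fwd) c = 5 - c;  // complement code: A<->T, C<->G
        fm.step(c, i, j);
        if (i >= j) { i = 0; j = 0; }
      } else {
        if (fwd) {
          fm.search(T.c_str() + p, k, i, j);
        } else {
          for (int t = 0; t < k; ++t) buf[t] = qcomp(T[p + k - 1 - t]);
          fm.search(buf.c_str(), k, i, j);
        }
        ++full;
        if (retry_pass) ++retried;
      }
      have = (i < j);
      int a = have ? interval_answer(fm, (Op)op, i, j) : -2;
      if (a != -2) {
        ans[p] = a;
        pending[p] = 0;
        if (bidir) bump(counter, fwd, sat);
      }
      prev_p = p;
    }
  };

  if (!bidir) {
    nblocks = 1;
    pass(0, tmax, true, false);
    for (int p = 0; p <= tmax; ++p)
      if (pending[p]) { ans[p] = negative_answer((Op)op); pending[p] = 0; }
  } else {
    int B = block_size;
    if (B < 1) stop("block size must be >= 1");
    for (int lo = 0; lo <= tmax; lo += B) {
      int hi = std::min(lo + B - 1, tmax);
      ++nblocks;
      bool first_fwd = counter >= 0;
      pass(lo, hi, first_fwd, false);
      bool any_pending = false;
      for (int p = lo; p <= hi; ++p) if (pending[p]) { any_pending = true; break; }
      if (any_pending) pass(lo, hi, !first_fwd, true);
      for (int p = lo; p <= hi; ++p)
        if (pending[p]) { ans[p] = negative_answer((Op)op); pending[p] = 0; }
    }
  }
  return List::create(_["answers"] = ans, _["full_searches"] = full,
                      _["extensions"] = ext, _["blocks"] = nblocks,
                      _["retried"] = retried, _["counter"] = counter);
}
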