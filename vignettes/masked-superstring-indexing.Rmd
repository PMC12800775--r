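---
title: "Indexing k-mer sets with masked superstrings and the Masked BWT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing k-mer sets with masked superstrings and the Masked BWT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskedBWT)
```

## The model

This package serves three query problems over a finite set $K$ of DNA
k-mers: membership (is $Q \in K$), compressed-dictionary queries (a
bijection $K \leftrightarrow \{0,\dots,|K|-1\}$ via `Lookup`/`Access`),
and streamed queries over all overlapping k-mers of a text. Two strand
models are supported. Under the *unidirectional* model k-mers are literal
strings; under the *bidirectional* model a k-mer and its reverse
complement are the same object, and the stored representative is the
**canonical** form, chosen here as the lexicographic minimum of the pair.
The choice of representative is a convention the data structure must fix
(dictionary hashes depend on it); lexicographic minimum is the common one
and makes hashes reproducible. Palindromic k-mers (possible at even $k$)
canonicalize to themselves; odd $k$ avoids them and is recommended for the
bidirectional model.

The central representation is the **masked superstring** $(S, M)$: $S$
contains every k-mer of $K$ as a substring (in either orientation under
the bidirectional model) and the bit mask $M$, of the same length,
declares which occurrences *represent* k-mers of $K$. Occurrences left
unmarked — in particular the "ghost" k-mers that the superstring
construction inevitably introduces — do not contribute to the represented
set. This one extra bit per character is what frees the representation
from any assumption about $(k-1)$-overlaps: any set, including uniformly
subsampled ones, is representable exactly.

Two mask normal forms matter. The **max-one** mask marks every occurrence
whose (canonical) k-mer is in $K$; it makes all mask bits inside one
suffix-array interval equal, so membership needs a single bit probe. The
**min-one** mask marks each k-mer exactly once; the rank of the mark then
numbers the k-mers $0,\dots,|K|-1$ in suffix-array order, which is the
dictionary hash. Among the equivalent min-one masks we deterministically
mark the *leftmost* occurrence (a scan-friendly choice; any single
occurrence would do). Both forms are recomputed by a single left-to-right
scan over $S$; the two-pass min-one-to-max-one conversion described for
the original tooling is replaced by this direct recomputation, and the
test suite verifies the two routes give identical masks.

## Superstring construction

`greedySuperstring()` implements the classic global greedy heuristic:
starting from the k-mers as singleton strings, merge the pair with the
longest suffix–prefix overlap until no positive overlap remains, then
concatenate. The heuristic leaves merge order at equal overlap length
unspecified, so this implementation fixes it: at each overlap length
$\ell = k-1, \dots, 1$ candidate left ends are processed in lexicographic
order of the oriented chain string (then orientation flag, then insertion
rank), and each left end takes the lexicographically smallest compatible
right end. Self-merges are forbidden, which excludes cycles; leftover
chains are concatenated in lexicographic order of their canonical
orientation. The construction is therefore a pure function of the k-mer
set.

Under the bidirectional model every chain is usable in both orientations;
a merge fixes the relative orientation of its two chains, and each
canonical k-mer is placed exactly once. Internally chains live in deques
with an orientation flag, the smaller chain is always merged into the
larger, and the ordering comparator short-circuits identical entries —
three choices that keep construction $O(\text{total length} \cdot \log)$
instead of quadratic.

On spectrum-like inputs (k-mers generated by a few long strings) the
greedy rediscovers the chains: for a single random sequence without
repeated $(k-1)$-mers the output length is exactly $|K| + k - 1$, and the
test suite asserts $|S| \le 1.1(|K| + k - 1)$ on a 50-kb genome at
$k = 31$. In the worst case (no overlaps at all) $|S| \le k|K|$. A
precomputed SPSS (unitigs, simplitigs, eulertigs) can be ingested directly
with `spssSuperstring()`, which masks the junction-spanning ghost windows
with zeros.

## The Masked Burrows-Wheeler Transform

`computeMBWT()` produces the pair $(S', M')$: $S'$ is the ordinary BWT of
$S$ with one terminal sentinel (`$`, smaller than every base, character
order `$ < A < C < G < T`), and $M'$ is the **SA-transformed mask**,
$M'[i] = M[SA[i]]$, with a zero appended for the sentinel position. The
definition can be phrased cyclically — rotate the mask one position left,
glue mask bits to characters, take the BWT comparing characters only, and
unzip; `mbwtCyclic()` implements that construction literally (it requires
a primitive string, i.e. distinct rotations) and the tests confirm it
agrees with the direct definition. The practical code path uses the
sentinel convention throughout, as FM-index practice does.

Suffix arrays are built by prefix doubling — worst-case-safe
$O(n \log^2 n)$ with no recursion — and the naive quadratic sort is kept
in the test helpers as the oracle. `invertMBWT()` restores $(S, M)$
exactly via the LF walk, reading each emitted character's mask bit at the
SA rank of the suffix starting at that position; round-trip identity over
random masked superstrings is part of the acceptance suite.

Rank and select over $S'$ and $M'$ are functional contracts here: full
cumulative occurrence tables are (re)built in $O(n)$ per query batch, and
physical succinctness is *not* attempted. Space is instead accounted
analytically by `spaceReport()`: the exact terms $2|S|$ bits (2-bit
characters with rank/select support) and $\log_2 \binom{|S|}{|M|_1}$ bits
(zeroth-order-entropy-compressed mask) are reported separately from an
`overhead_bits` field, which models sampled 32-bit occurrence checkpoints
every 64 positions plus the counts table (plus the kLCP bit vector when
built). The mask term is computed through `lchoose()`, so it never
overflows. Since $\log_2 \binom{n}{m} \le n$, the two exact terms never
exceed $3|S|$ bits.

## Queries

All queries start with backward search (`backwardSearch()`), updating the
interval through the counts table — which includes the sentinel, so
`counts["A"]` is 1 plus nothing smaller and no special-casing is needed —
with an early exit on an empty interval. Intervals, hashes and all
reported coordinates are 0-based and half-open.

The printed one-line form of the membership rule in the source material
reads as requiring $i = j$; that contradicts the surrounding non-empty
interval semantics and is treated as a typo: membership is
$i \ne j \wedge M'[i] = 1$.

Under the bidirectional model a query k-mer may sit in $S$ in either
orientation, so the search tries one strand and falls back to the other.
Which strand goes first is decided by a **saturating strand counter**
(bounds $\pm 7$): +1 on a forward hit, −1 on a reverse-complement hit,
predict forward when non-negative. The original implementation keeps two
counters accumulated separately per direction; the published description
leaves their interaction ambiguous, so this package collapses them into
the single signed counter above — correctness is strand-order-independent
either way, and the tests verify answers are identical with the counter
pinned to either extreme. `kmerLookup()` must check the second strand
whenever the first interval carries no mask 1, because the single min-one
mark lives on exactly one strand's interval.

Dictionary hashes are stable for a fixed index but not canonical across
different superstrings of the same set: min-one mark placement and
suffix-array order fix them.

## Streaming

`buildKLCP()` thresholds Kasai-computed adjacent LCPs at $k-1$: bit $t$
says the suffixes of rank $t$ and $t+1$ share a $(k-1)$-prefix. Extending
a positive k-mer's interval through the surrounding 1-run (linear scans to
the flanking zeros by default; an equivalent rank/select formulation is
provided behind the same contract) yields its $(k-1)$-prefix interval, so
the next overlapping k-mer costs one extension plus one backward-search
step. Within a strand pass the text is traversed in backward-search order
— right to left on the forward strand, left to right on the reverse
strand, where the prepended character is the complement of the entering
base.

Bidirectional texts are split into blocks; each block is queried entirely
on the strand the counter predicts, and only the positions not found
there are retried on the other strand (chained where adjacent). The
published block size ("parts of size $\lfloor 2\ell \rfloor$") is
dimensionally inconsistent as printed, while the accompanying proof uses
$B = \min(t, k)$; this package defaults to
$B = \max(k, \lfloor 2\sqrt{|T|} \rfloor)$, matching the proof's
square-root flavor, and exposes it as `blockSize` — answers are provably
independent of $B$ and of the counter state; only telemetry varies, which
the tests assert.

Telemetry makes the amortization countable: a fully positive
unidirectional stream costs exactly one full backward search regardless of
length. For the deferred-retry block heuristic, a position missing from
the first-queried strand costs at most two extra full searches (its own
retry plus the re-seed of the broken chain), so the tested bound is
$\text{full} \le \#\text{blocks} + 2 \cdot \#\text{not found on the first
strand}$; on strand-consistent positive streams the exact form
$\text{full} = \#\text{blocks}$ holds for the correct initial prediction.
A wrong initial prediction makes the first block pay one search per
position — the expected constant-size startup cost — after which the
counter saturates and locks on. Windows containing non-ACGT letters
answer negatively and reset the chain; the published method leaves
N-handling unspecified.

## Degenerate inputs and numerical choices

The empty k-mer set yields the empty masked superstring, whose index
answers false/−1 to everything. Strings shorter than $k$ carry no windows,
so their mask bits are structurally unconstrained; for $|S| \ge k$ the
last $k-1$ bits must be zero and the class validity enforces it.
Non-ACGT letters are upcased where harmless (plain FASTA ingestion) and
either skipped window-wise (k-mer extraction, the default, mirroring
common k-mer tooling) or rejected (`strict = TRUE`). `Access` with an
out-of-range hash is an error, as is a policy/mode mismatch at index
construction unless the caller opts into the general-mask query path.

## The fixture generator

`generateFixture()` emulates the study conditions the package is tested
under: `random_genome` (uniform ACGT, one long chain — the spectrum-like
best case), `pangenome` (one base genome plus $g-1$ mutants with i.i.d.
substitutions at rate $\mu$, emulating high-diversity collections; the
default $\mu = 0.01$ is a realistic per-base polymorphism density for a
diverse microbial pangenome), `random_kmers` (uniform k-mers, the
overlap-free worst case for de-Bruijn-graph methods), and `subsampled`
(any of the above through uniform subsampling, default 10%, the published
subsampling regime). All draws are deterministic given the seed. What the
generator does **not** emulate: sequencing errors with realistic error
profiles, repeat structure of real genomes, GC bias, and coverage-driven
k-mer frequency distributions. Passing tests therefore demonstrate
correctness of the data structure on structurally diverse sets, not
biological realism of the inputs; correctness is input-agnostic, so this
is the right trade.

The test suite runs 20 fixtures with $k \in \{5, 7, 11, 15, 31\}$ —
genomes up to 50 kb, pangenomes up to 8 genomes, random sets up to 5000
k-mers, subsampled variants, both strand models — with membership checked
against a hash-set oracle exhaustively over all $4^k$ k-mers for
$k \le 8$ and against $10^4$ random probes otherwise. These sizes keep
the whole suite around a minute while still exercising every regime the
method distinguishes.

## Known limitations

Construction is in-memory and single-threaded; terabyte-scale BWT
construction and parallel queries are out of scope. Rank/select is not
physically succinct (space is accounted, not realized), no payload arrays
are attached to dictionary hashes, and the index is static — changing the
set means rebuilding. The greedy heuristic has no approximation guarantee
against an arbitrary SPSS under heavy de-Bruijn-graph branching (very
small $k$), though the $k|K|$ bound and exact decodability always hold.
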