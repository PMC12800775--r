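# maskedBWT

Space-efficient indexing of arbitrary DNA k-mer sets via masked
superstrings and the Masked Burrows-Wheeler Transform (MBWT).

## The problem

Modern sequence analysis tokenizes genomes, pangenomes, transcriptomes and
read sets into *k-mers* (length-k strings over `{A,C,G,T}`) and then needs
three low-level operations on a k-mer set K:

* **Membership** — `Member(Q)`: is the k-mer Q in K?
* **Dictionary** — `Lookup(Q)` / `Access(h)`: a bijection between K and the
  hash range `{0, ..., |K|-1}` (a minimal perfect hash with rejection and
  its inverse), enabling associated payload arrays.
* **Streaming** — amortized O(1) queries over the consecutive overlapping
  k-mers of a query sequence.

Indexes built on de Bruijn graph paths (unitigs/simplitigs) compress well
only when most k-mers share (k-1)-long overlaps; subsampled, sketched, or
highly polymorphic sets break that assumption. This package indexes
*masked superstrings* instead, which exploit overlaps of **every** length
and therefore stay compact on arbitrary k-mer sets.

## The method

A **masked superstring** of K is a pair (S, M): a superstring S containing
every k-mer of K as a substring (in either orientation under the
bidirectional model, where Q and its reverse complement are one object),
and a bit mask M with `|M| = |S|`. A k-mer is *represented* iff at least
one of its occurrences carries mask bit 1; other occurrences — including
"ghost" k-mers introduced by the superstring — carry 0. S is built by the
classic global greedy heuristic (merge strings by decreasing suffix-prefix
overlap), giving `|S| ≈ |K| + k - 1` on spectrum-like sets and `|S| ≤ k|K|`
always. The mask is then optimized per use case: **max-one** (every
represented occurrence marked) for membership, **min-one** (exactly one
mark per k-mer, at its leftmost occurrence) for dictionaries.

The index is the **Masked BWT**: the BWT S' of S plus a sentinel, paired
with the SA-transformed mask `M'[i] = M[SA[i]]`. Backward search on S'
yields a k-mer's suffix-array interval `[i, j)`; then

* `Member`: with a max-one mask all of `M'[i..j)` agree, so the answer is
  the single bit `M'[i]` (with arbitrary masks: `rank1(M', j) > rank1(M', i)`);
* `Lookup`: with a min-one mask, `rank1(M', i)` is the k-mer's unique
  minimal hash, `-1` when the interval carries no 1;
* `Access(h)`: `select1(M', h)` locates the marked row, and k steps of
  first-column + select on S' spell the k-mer back out.

Space is `2|S| + log2 C(|S|, |M|₁) + o(|S|)` bits — at most `(3 + o(1))|S|`,
and `2 + o(1)` bits per distinct canonical k-mer when `|S| = |K| + o(|K|)`.

Streamed queries use a **kLCP** bit vector (bit t = 1 iff suffixes of rank
t and t+1 share a (k-1)-prefix): after a positive k-mer, the next one costs
one kLCP range extension plus a single backward-search step. Under the
bidirectional model the query is split into blocks whose search strand is
predicted by a saturating counter (±7).

## Worked example

```r
library(maskedBWT)

ks <- extractKmers(c("TGGATGCAAGCT", "GCGTAACGT"), k = 5, model = "bidirectional")
ks
#> KmerSet: 13 distinct 5-mers (bidirectional model)
#>    AACGT AAGCT ATCCA ATGCA CAAGC ...

ms <- greedySuperstring(ks)
ms
#> MaskedSuperstring: |S| = 20, 13 mask 1s, k = 5 (bidirectional, min-one)
#>   AGCTTGCATCCACGTTACGC
#>   11111111000111110000
```

Thirteen 5-mers collapse into a 20-character superstring; the min-one mask
marks each exactly once (13 ones), and the trailing/ghost windows carry 0.

```r
idx <- buildIndex(applyMaskPolicy(ms, "max-one"), "memb", withKLCP = TRUE)
kmerMember(idx, c("TGCAA", "TTGCA", "ACGTA"))
#> [1]  TRUE  TRUE FALSE
```

`TTGCA` is the reverse complement of `TGCAA`, hence equal to it under the
bidirectional model; `ACGTA` is absent.

```r
dict <- buildIndex(ms, "dict")
kmerLookup(dict, kmers(ks))
#>  [1]  0  1  2 10  7  3 11  4  5  6  9  8 12
kmerAccess(dict, 0:2)
#> [1] "ACGTT" "AGCTT" "ATCCA"
```

Lookup maps the 13 k-mers bijectively onto 0..12 (−1 for absent k-mers);
Access inverts it, returning each k-mer in superstring orientation.

```r
res <- streamQuery(idx, "TGGATGCAAGCT")
streamAnswers(res)
#> [1] TRUE TRUE TRUE TRUE TRUE TRUE TRUE TRUE
telemetry(res)$full_searches
#> [1] 8

spaceReport(idx, length(ks))$bits_per_kmer
#> [1] 4.326329
```

All 8 overlapping 5-mers of the query are present. On this tiny
mixed-orientation superstring every window pays a full search; on long
strand-consistent streams the kLCP chain reduces that to one full search
per strand run (the acceptance script demonstrates 1 full search for
49,970 k-mers). The space report gives the two analytic terms
(`2|S| = 40` bits, `log2 C(20, 13) ≈ 16.2` bits) per k-mer.

A command-line interface wrapping the same functions ships in
`inst/scripts/maskedBWT-cli` (verbs `index`, `query`, `lookup`, `access`,
`export`, `fixture`).

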