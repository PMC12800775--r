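# FM-index style query structures over the MBWT: membership (max-one mask),
# compressed dictionary (min-one mask), strand prediction, space accounting.

#' Build a query index from a masked superstring
#'
#' Constructs the MBWT image with its counts table and (lazily) rank/select
#' support. `mode = "memb"` serves membership queries and requires a
#' max-one mask; `mode = "dict"` serves Lookup/Access and requires a
#' min-one mask. A mismatched policy is a configuration error unless
#' `generalMask = TRUE`, which enables the slower general-mask query path
#' ([kmerMemberGeneral()]) for arbitrary masks. With `withKLCP = TRUE` the
#' kLCP bit vector for streamed queries is built alongside.
#'
#' @param ms a [MaskedSuperstring-class].
#' @param mode `"memb"` or `"dict"`.
#' @param withKLCP build the kLCP array for [streamQuery()].
#' @param generalMask opt in to general-mask queries with any mask policy.
#' @return an [MBWTIndex-class].
#' @examples
#' ms <- maskedSuperstring("ACGT", "1100", k = 3, policy = "max-one")
#' idx <- buildIndex(ms, "memb")
#' kmerMember(idx, c("ACG", "AAA"))
#' @export
buildIndex <- function(ms, mode = c("memb", "dict"), withKLCP = FALSE,
                       generalMask = FALSE) {
  stopifnot(is(ms, "MaskedSuperstring"))
  mode <- match.arg(mode)
  needed <- if (mode == "memb") "max-one" else "min-one"
  if (!generalMask && !identical(ms@policy, needed))
    stop(sprintf("mode '%s' requires a %s mask; got '%s' (set generalMask = TRUE, or applyMaskPolicy() first)",
                 mode, needed, ms@policy))
  built <- .mbwt_image(ms@S, ms@M, ms@k, ms@model, ms@policy)
  klcp <- logical(0)
  if (withKLCP) {
    lcp <- cpp_lcp_adjacent(ms@S, built$sa)
    klcp <- lcp >= ms@k - 1L
    klcp[length(klcp)] <- FALSE
  }
  state <- new.env(parent = emptyenv())
  state$counter <- 0L
  new("MBWTIndex", image = built$img, mode = mode,
      general = isTRUE(generalMask), klcp = klcp, state = state)
}

#' One-call index construction from a k-mer set
#'
#' Convenience pipeline: greedy masked superstring, mask optimization for
#' the target mode (max-one for `"memb"`, min-one for `"dict"`), index
#' construction.
#'
#' @param x a [KmerSet-class].
#' @inheritParams buildIndex
#' @return an [MBWTIndex-class].
#' @export
indexKmerSet <- function(x, mode = c("memb", "dict"), withKLCP = FALSE) {
  mode <- match.arg(mode)
  ms <- greedySuperstring(x)
  if (mode == "memb") ms <- applyMaskPolicy(ms, "max-one")
  buildIndex(ms, mode, withKLCP = withKLCP)
}

#' Backward search for a pattern's suffix-array interval
#'
#' Starting from the full interval `[0, n)`, processes the characters of `Q`
#' in reverse; for each character c the interval is updated through the
#' counts table and rank on `S'`, with an early exit to the empty interval
#' `(0, 0)`. The result is the interval of suffixes having `Q` as a prefix.
#'
#' @param index an [MBWTIndex-class].
#' @param Q pattern over \{A,C,G,T\}, `nchar(Q) <= k`.
#' @return integer `c(i, j)`: 0-based half-open interval.
#' @examples
#' idx <- indexKmerSet(kmerSet(c("ACG", "CGT")), "memb")
#' backwardSearch(idx, "ACG")  # [1, 2)
#' @export
backwardSearch <- function(index, Q) {
  stopifnot(is(index, "MBWTIndex"), length(Q) == 1L)
  Q <- toupper(Q)
  assert_dna(Q, "query")
  img <- index@image
  res <- cpp_backward_search(img@codes, as.integer(img@mprime), Q)
  as.integer(res)
}

.batch_query <- function(index, Q, op, counter) {
  img <- index@image
  Q <- toupper(as.character(Q))
  if (any(nchar(Q) != img@k))
    stop(sprintf("queries must have length k = %d", img@k))
  assert_dna(Q, "query")
  use_state <- is.null(counter)
  counter0 <- if (use_state) index@state$counter else as.integer(counter)
  res <- cpp_query_batch(img@codes, as.integer(img@mprime), Q, img@k,
                         img@model == "bidirectional", op, counter0, 7L)
  if (use_state) index@state$counter <- res$counter
  res$answers
}

#' Membership query (Member)
#'
#' Is each query k-mer in the represented set? Requires `mode = "memb"`
#' (max-one mask): inside a non-empty backward-search interval all mask
#' bits agree, so inspecting the first bit suffices. Under the
#' bidirectional model the strand suggested by the saturating counter is
#' searched first and the other strand is tried whenever the first yields
#' an empty interval or bit 0; the counter moves +1 on a forward hit, -1
#' on a reverse-complement hit (saturating at +/-7). The strand order only
#' affects which search runs first, never the answer.
#'
#' @param index an [MBWTIndex-class] in `"memb"` mode.
#' @param Q character vector of k-mers.
#' @param counter override the strand counter for this call (integer in
#'   `[-7, 7]`); by default the index's persistent counter is used and
#'   updated.
#' @return logical vector.
#' @export
kmerMember <- function(index, Q, counter = NULL) {
  stopifnot(is(index, "MBWTIndex"))
  if (index@mode != "memb")
    stop("kmerMember() requires an index built in 'memb' mode")
  if (index@image@policy != "max-one")
    return(kmerMemberGeneral(index, Q, counter))
  .batch_query(index, Q, 0L, counter) == 1L
}

#' Membership query with an arbitrary mask (general-mask path)
#'
#' Works for any mask policy at the cost of two rank operations on `M'`:
#' a k-mer is present iff its interval (on either strand under the
#' bidirectional model) contains at least one mask 1. Agrees with
#' [kmerMember()] on max-one indexes.
#'
#' @inheritParams kmerMember
#' @return logical vector.
#' @export
kmerMemberGeneral <- function(index, Q, counter = NULL) {
  stopifnot(is(index, "MBWTIndex"))
  .batch_query(index, Q, 1L, counter) == 1L
}

#' Dictionary hash query (Lookup)
#'
#' Returns each k-mer's unique minimal hash, or -1 when absent. Requires
#' `mode = "dict"` (min-one mask): the single marked occurrence makes
#' `rank1(M', i)` the number of distinct represented k-mers preceding the
#' query in SA order, so over the represented set the hashes are exactly
#' `0 .. |K|-1`, each once. Under the bidirectional model the predicted
#' strand is tried first, and the second strand is checked whenever the
#' first interval carries no 1 (the single mark lives on exactly one
#' strand's interval).
#'
#' @inheritParams kmerMember
#' @param index an [MBWTIndex-class] in `"dict"` mode.
#' @return integer vector of hashes in `0 .. |K|-1`, or -1 for absent
#'   k-mers. Hashes are stable for a fixed index but not canonical across
#'   different superstrings of the same set.
#' @export
kmerLookup <- function(index, Q, counter = NULL) {
  stopifnot(is(index, "MBWTIndex"))
  if (index@mode != "dict")
    stop("kmerLookup() requires an index built in 'dict' mode")
  .batch_query(index, Q, 2L, counter)
}

#' Dictionary access query (Access)
#'
#' Inverse of [kmerLookup()]: reconstructs the k-mer with hash `h`. Selects
#' the h-th 1 of `M'`, then walks k steps through the first-column
#' character (located via the counts table) and select on `S'`. The k-mer
#' is returned in superstring orientation, so under the bidirectional model
#' `kmerAccess(index, kmerLookup(index, Q))` is `Q` or its reverse
#' complement, and `kmerLookup(index, kmerAccess(index, h)) == h`.
#'
#' @param index an [MBWTIndex-class] in `"dict"` mode.
#' @param h integer vector of hashes, each in `[0, popcount(M'))`.
#' @return character vector of k-mers.
#' @export
kmerAccess <- function(index, h) {
  stopifnot(is(index, "MBWTIndex"))
  if (index@mode != "dict")
    stop("kmerAccess() requires an index built in 'dict' mode")
  img <- index@image
  h <- as.integer(h)
  if (anyNA(h)) stop("hashes must be integers")
  cpp_access_batch(img@codes, as.integer(img@mprime), h, img@k)
}

#' Analytic space accounting for an index
#'
#' Reports the two exact terms of the space bound -- `2|S|` bits for the
#' superstring and `log2 C(|S|, |M|_1)` bits for the zeroth-order-entropy-
#' compressed mask -- their sum, and the per-k-mer cost. Rank/select
#' bookkeeping (the `o(|S|)` term, implementation-defined) is reported
#' separately as `overhead_bits`, modeled as sampled 32-bit occurrence
#' checkpoints every 64 positions plus the counts table, with the optional
#' kLCP bit vector on top. `superstring_bits + mask_bits <= 3|S|` always.
#'
#' @param index an [MBWTIndex-class].
#' @param kSize number of distinct (canonical) k-mers represented; when 0
#'   the `bits_per_kmer` field is omitted.
#' @return named list: `superstring_bits`, `mask_bits`, `total_bits`,
#'   `bits_per_kmer` (absent if `kSize == 0`), `overhead_bits`.
#' @export
spaceReport <- function(index, kSize) {
  stopifnot(is(index, "MBWTIndex"))
  img <- index@image
  n <- length(img@codes)          # |S| + 1 (sentinel)
  slen <- n - 1L
  ones <- sum(img@mprime)
  out <- list(
    superstring_bits = 2 * slen,
    mask_bits = maskEntropyBits(slen, min(ones, slen)),
    overhead_bits = 4 * 32 * ceiling(n / 64) + 6 * 64 + length(index@klcp)
  )
  out$total_bits <- out$superstring_bits + out$mask_bits
  if (kSize > 0) out$bits_per_kmer <- out$total_bits / kSize
  out[c("superstring_bits", "mask_bits", "total_bits",
        if (kSize > 0) "bits_per_kmer", "overhead_bits")]
}

#' Saturating strand predictor
#'
#' Constructs a [StrandPredictor-class] with the given counter value.
#' `predictStrand()` returns `"forward"` when the counter is >= 0 and
#' `"reverse"` otherwise; `updatePredictor()` moves the counter one step
#' toward the strand a k-mer was found on, saturating at +/-7.
#'
#' @param counter initial counter value in `[-7, 7]`.
#' @return a [StrandPredictor-class].
#' @export
strandPredictor <- function(counter = 0L) {
  new("StrandPredictor", counter = as.integer(counter), saturation = 7L)
}

#' @rdname strandPredictor
#' @param x a [StrandPredictor-class].
#' @export
predictStrand <- function(x) {
  stopifnot(is(x, "StrandPredictor"))
  if (x@counter >= 0L) "forward" else "reverse"
}

#' @rdname strandPredictor
#' @param strand `"forward"` or `"reverse"`: the strand the k-mer was
#'   found on.
#' @export
updatePredictor <- function(x, strand = c("forward", "reverse")) {
  stopifnot(is(x, "StrandPredictor"))
  strand <- match.arg(strand)
  cnt <- x@counter + if (strand == "forward") 1L else -1L
  cnt <- max(min(cnt, x@saturation), -x@saturation)
  new("StrandPredictor", counter = cnt, saturation = x@saturation)
}

#' @describeIn accessors k-mer length of an `MBWTIndex`.
#' @export
setMethod("kmerLength", "MBWTIndex", function(x) x@image@k)
#' @describeIn accessors strand model of an `MBWTIndex`.
#' @export
setMethod("strandModel", "MBWTIndex", function(x) x@image@model)
#' @describeIn accessors mask policy of an `MBWTIndex`.
#' @export
setMethod("maskPolicy", "MBWTIndex", function(x) x@image@policy)
#' @describeIn accessors query mode (`"memb"` or `"dict"`).
#' @export
setMethod("indexMode", "MBWTIndex", function(x) x@mode)
#' @describeIn accessors the kLCP bit vector of an `MBWTIndex` (length 0
#'   when not built).
#' @export
setMethod("klcpBits", "MBWTIndex", function(x) x@klcp)

setMethod("show", "MBWTIndex", function(object) {
  img <- object@image
  cat(sprintf("MBWTIndex (%s): n = %d, k = %d, %s model, %s mask%s\n",
              object@mode, length(img@codes), img@k, img@model, img@policy,
              if (length(object@klcp) > 0) ", with kLCP" else ""))
})
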