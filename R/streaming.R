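# kLCP array and amortized streamed queries over all overlapping k-mers of a
# query text.

#' Build the kLCP bit vector
#'
#' Bit t is 1 iff the suffixes of rank t and t+1 of S plus sentinel share a
#' common prefix of length at least k-1; the last bit is 0. Computed by
#' Kasai's LCP algorithm thresholded at k-1. A positive k-mer's SA interval
#' extended through the surrounding 1-run is exactly the interval of its
#' (k-1)-long prefix, which is what makes O(1)-amortized streamed extension
#' possible.
#'
#' @param sa a [SuffixArray-class].
#' @param k k-mer length (>= 2).
#' @return a [KLCP-class].
#' @examples
#' klcpBits(buildKLCP(buildSuffixArray("AAAA"), k = 3))  # 0 0 1 1 0
#' @export
buildKLCP <- function(sa, k) {
  stopifnot(is(sa, "SuffixArray"))
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  lcp <- cpp_lcp_adjacent(sa@s, sa@sa)
  bits <- lcp >= k - 1L
  bits[length(bits)] <- FALSE
  new("KLCP", bits = bits, k = k)
}

#' @describeIn accessors the bit vector of a `KLCP`.
#' @export
setMethod("klcpBits", "KLCP", function(x) x@bits)
#' @describeIn accessors k-mer length of a `KLCP`.
#' @export
setMethod("kmerLength", "KLCP", function(x) x@k)

setMethod("show", "KLCP", function(object) {
  cat(sprintf("KLCP: %d bits (%d ones), k = %d\n", length(object@bits),
              sum(object@bits), object@k))
})

#' Extend a k-mer interval to its (k-1)-prefix interval
#'
#' Given the non-empty SA interval of a k-mer present in the superstring,
#' returns the maximal enclosing interval whose internal kLCP bits are all
#' 1: the SA interval of the k-mer's (k-1)-long prefix. The default
#' implementation scans linearly to the flanking 0 bits (no rank/select
#' needed); `method = "rankselect"` computes the same interval through
#' rank and select over the kLCP bits. Idempotent.
#'
#' @param index an [MBWTIndex-class] built with `withKLCP = TRUE`.
#' @param interval integer `c(i, j)`, a non-empty 0-based half-open
#'   interval as returned by [backwardSearch()].
#' @param method `"scan"` or `"rankselect"`.
#' @return integer `c(i, j)` of the extended interval.
#' @export
extendToPrefixInterval <- function(index, interval,
                                   method = c("scan", "rankselect")) {
  stopifnot(is(index, "MBWTIndex"))
  method <- match.arg(method)
  if (length(index@klcp) == 0) stop("index was built without a kLCP array")
  i <- as.integer(interval[1]); j <- as.integer(interval[2])
  n <- length(index@klcp)
  if (!(i >= 0 && i < j && j <= n)) stop("interval must be non-empty and within [0, n)")
  bits <- index@klcp
  if (method == "scan") {
    while (i > 0 && bits[i]) i <- i - 1L            # bits[i] is kLCP[i-1] (1-based R)
    while (j < n && bits[j]) j <- j + 1L
  } else {
    zeros0 <- c(0L, cumsum(!bits))                  # rank0 over 0-based prefixes
    sel0 <- which(!bits) - 1L                       # 0-based positions of 0 bits
    r <- zeros0[i + 1L]                             # rank0(i)
    i <- if (r == 0L) 0L else sel0[r] + 1L
    j <- sel0[zeros0[j] + 1L] + 1L                  # first 0 at or after j-1, then +1
  }
  c(i, j)
}

#' Streamed queries over all k-mers of a text
#'
#' Answers Member (or Lookup) for every k-mer start of `T`, each answer
#' equal to the isolated-query answer, in amortized constant time per
#' positive k-mer. Within a strand pass the text is traversed in
#' backward-search order; after a k-mer found in the superstring, the next
#' answer costs one kLCP range extension plus a single backward-search
#' step, while a k-mer absent from the superstring breaks the chain and
#' the next position pays a full O(k) backward search. Under the
#' bidirectional model the text is split into blocks (default size
#' `max(k, floor(2 * sqrt(nchar(T))))`); each block is queried entirely on
#' the strand predicted by the saturating counter, and only the positions
#' not found there are retried on the other strand. Windows containing
#' non-ACGT letters answer negatively and reset the chain. Answers are
#' independent of the block size and of the counter state; only telemetry
#' varies.
#'
#' @param index an [MBWTIndex-class] built with `withKLCP = TRUE`.
#' @param text query text, `nchar(text) >= k` for a non-empty result.
#' @param op `"member"` or `"lookup"` (`"lookup"` needs `"dict"` mode).
#' @param blockSize block length for the bidirectional strand heuristic;
#'   `NULL` for the default.
#' @param counter override the strand counter for this call; by default the
#'   index's persistent counter is used and updated.
#' @return a [StreamResult-class]; see [streamAnswers()] and [telemetry()].
#'   Telemetry reports `full_searches`, `extensions`, `blocks` and
#'   `retried` (positions retried on the second strand).
#' @examples
#' idx <- indexKmerSet(kmerSet(c("ACG", "CGT")), "memb", withKLCP = TRUE)
#' res <- streamQuery(idx, "ACGT")
#' streamAnswers(res)               # TRUE TRUE
#' telemetry(res)$full_searches    # 1: the second answer reused the chain
#' @export
streamQuery <- function(index, text, op = c("member", "lookup"),
                        blockSize = NULL, counter = NULL) {
  stopifnot(is(index, "MBWTIndex"))
  op <- match.arg(op)
  if (length(index@klcp) == 0) stop("index was built without a kLCP array")
  text <- toupper(as.character(text))
  stopifnot(length(text) == 1L)
  img <- index@image
  cop <- if (op == "lookup") {
    if (index@mode != "dict") stop("streamed lookup requires an index in 'dict' mode")
    2L
  } else if (img@policy == "max-one") 0L else 1L
  if (is.null(blockSize))
    blockSize <- max(img@k, floor(2 * sqrt(nchar(text))))
  blockSize <- as.integer(blockSize)
  if (is.na(blockSize) || blockSize < 1L) stop("blockSize must be >= 1")
  use_state <- is.null(counter)
  counter0 <- if (use_state) index@state$counter else as.integer(counter)
  res <- cpp_stream_query(img@codes, as.integer(img@mprime), index@klcp,
                          text, img@k, img@model == "bidirectional", cop,
                          blockSize, counter0, 7L)
  if (use_state) index@state$counter <- res$counter
  new("StreamResult", op = op, answers = res$answers,
      telemetry = list(full_searches = res$full_searches,
                       extensions = res$extensions,
                       blocks = res$blocks, retried = res$retried,
                       counter = res$counter))
}

#' @describeIn accessors per-position answers of a `StreamResult` (logical
#'   for member, integer hashes / -1 for lookup).
#' @export
setMethod("streamAnswers", "StreamResult", function(x) {
  if (x@op == "member") x@answers == 1L else x@answers
})
#' @describeIn accessors operation-count telemetry of a `StreamResult`.
#' @export
setMethod("telemetry", "StreamResult", function(x) x@telemetry)

setMethod("show", "StreamResult", function(object) {
  cat(sprintf("StreamResult (%s): %d answers (%d positive); %d full searches, %d extensions\n",
              object@op, length(object@answers),
              sum(object@answers >= if (object@op == "member") 1L else 0L),
              object@telemetry$full_searches, object@telemetry$extensions))
})
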