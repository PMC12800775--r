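#' KmerSet: a set of DNA k-mers under a strand model
#'
#' Holds a finite set of distinct k-mers over \{A,C,G,T\} together with the
#' k-mer length `k` and the strand model. Under the bidirectional model a
#' k-mer and its reverse complement are the same object and every stored
#' member is its own canonical (lexicographically minimal) form; under the
#' unidirectional model k-mers are taken literally.
#'
#' @slot k integer k-mer length (>= 2).
#' @slot model `"unidirectional"` or `"bidirectional"`.
#' @slot kmers sorted character vector of distinct k-mers.
#' @seealso [kmerSet()], [extractKmers()], [subsampleKmers()]
#' @exportClass KmerSet
setClass("KmerSet",
  representation(k = "integer", model = "character", kmers = "character"))

setValidity("KmerSet", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 2L)
    msg <- c(msg, "k must be a single integer >= 2")
  if (!object@model %in% c("unidirectional", "bidirectional"))
    msg <- c(msg, "model must be 'unidirectional' or 'bidirectional'")
  if (length(object@kmers) > 0) {
    if (!all(nchar(object@kmers) == object@k))
      msg <- c(msg, "all k-mers must have length exactly k")
    if (!all(is_dna(object@kmers)))
      msg <- c(msg, "k-mers must be over {A,C,G,T}")
    if (anyDuplicated(object@kmers))
      msg <- c(msg, "k-mers must be distinct")
    if (is.unsorted(object@kmers))
      msg <- c(msg, "k-mers must be stored sorted")
    if (object@model == "bidirectional" &&
        !identical(unname(object@kmers), unname(cpp_canonical(object@kmers))))
      msg <- c(msg, "bidirectional members must equal their canonical form")
  }
  if (length(msg)) msg else TRUE
})

#' MaskedSuperstring: a superstring plus a represented-occurrence mask
#'
#' The pair (S, M): a superstring `S` over \{A,C,G,T\} and a bit mask `M`
#' of the same length. A k-mer is represented iff at least one of its
#' occurrences (in either orientation under the bidirectional model) carries
#' mask bit 1; occurrences of unrepresented ("ghost") k-mers all carry 0.
#' The mask `policy` records whether the mask is in min-one form (each
#' represented k-mer marked exactly once, at its leftmost occurrence),
#' max-one form (every represented occurrence marked), or unoptimized.
#'
#' @slot S character scalar, the superstring.
#' @slot M logical vector, `length(M) == nchar(S)`; the last k-1 bits are 0.
#' @slot k,model as in [KmerSet-class].
#' @slot policy `"min-one"`, `"max-one"` or `"unoptimized"`.
#' @seealso [maskedSuperstring()], [greedySuperstring()], [applyMaskPolicy()]
#' @exportClass MaskedSuperstring
setClass("MaskedSuperstring",
  representation(S = "character", M = "logical", k = "integer",
                 model = "character", policy = "character"))

setValidity("MaskedSuperstring", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 2L)
    msg <- c(msg, "k must be a single integer >= 2")
  if (!object@model %in% c("unidirectional", "bidirectional"))
    msg <- c(msg, "invalid strand model")
  if (!object@policy %in% c("min-one", "max-one", "unoptimized"))
    msg <- c(msg, "invalid mask policy")
  if (length(object@S) != 1L || is.na(object@S))
    msg <- c(msg, "S must be a single string")
  else {
    if (!is_dna(object@S)) msg <- c(msg, "S must be over {A,C,G,T}")
    n <- nchar(object@S)
    if (length(object@M) != n) {
      msg <- c(msg, "mask length must equal superstring length")
    } else if (n >= object@k && any(object@M[seq(n - object@k + 2L, n)])) {
      # strings shorter than k carry no windows; their bits are unconstrained
      msg <- c(msg, "the last k-1 mask bits must be 0 (no k-mer starts there)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SuffixArray: sorted suffixes of a superstring plus sentinel
#'
#' The suffix array of `S` with a terminal sentinel `$` appended, `$` sorting
#' before every base. `sa` holds 0-based starting positions of the suffixes
#' in increasing lexicographic order, so `sa[1] == nchar(S)` (the sentinel
#' suffix).
#'
#' @slot s character scalar: the string (without the sentinel).
#' @slot sa integer vector: 0-based suffix starting positions.
#' @seealso [buildSuffixArray()], [buildKLCP()]
#' @exportClass SuffixArray
setClass("SuffixArray", representation(s = "character", sa = "integer"))

setValidity("SuffixArray", function(object) {
  n <- nchar(object@s) + 1L
  if (length(object@sa) != n) return("sa must have length nchar(s) + 1")
  if (!identical(sort(object@sa), 0:(n - 1L))) return("sa must be a permutation of 0..n-1")
  if (object@sa[1] != n - 1L) return("sa[1] must be the sentinel suffix")
  TRUE
})

#' MBWTImage: the Masked Burrows-Wheeler Transform of a masked superstring
#'
#' The pair (S', M'): `S'` is the BWT of S plus sentinel and `M'` is the
#' SA-transformed mask, i.e. `M'[i] = M[j]` where `j` is the starting
#' position of the i-th lexicographically smallest suffix (the sentinel
#' position carries an appended 0). Character counts and rank/select support
#' are derived from the image on demand.
#'
#' @slot codes integer vector of BWT symbol codes ($=0, A=1, C=2, G=3, T=4).
#' @slot mprime logical vector, the SA-transformed mask.
#' @slot counts named integer vector: for each symbol c, the number of text
#'   characters strictly smaller than c (sentinel included).
#' @slot k,model,policy carried over from the source [MaskedSuperstring-class].
#' @slot support environment caching occurrence tables (internal).
#' @seealso [computeMBWT()], [invertMBWT()], [mbwtRank()], [mbwtSelect()]
#' @exportClass MBWTImage
setClass("MBWTImage",
  representation(codes = "integer", mprime = "logical", counts = "integer",
                 k = "integer", model = "character", policy = "character",
                 support = "environment"))

setValidity("MBWTImage", function(object) {
  msg <- character(0)
  if (length(object@codes) != length(object@mprime))
    msg <- c(msg, "codes and mprime must have equal length")
  if (sum(object@codes == 0L) != 1L)
    msg <- c(msg, "image must contain exactly one sentinel")
  if (any(object@codes < 0L | object@codes > 4L))
    msg <- c(msg, "invalid symbol codes")
  cnt <- tabulate(object@codes + 1L, nbins = 5L)
  if (!identical(unname(object@counts), c(0L, cumsum(cnt)[-5L])))
    msg <- c(msg, "counts table inconsistent with the image")
  if (length(msg)) msg else TRUE
})

#' MBWTIndex: FM-index style query structure over an MBWT image
#'
#' The queryable index: an [MBWTImage-class] plus the query mode
#' (`"memb"` for membership with a max-one mask, `"dict"` for
#' Lookup/Access with a min-one mask), an optional kLCP bit vector for
#' streamed queries, and a saturating strand counter (|counter| <= 7) used
#' to predict which strand to search first under the bidirectional model.
#'
#' @slot image the [MBWTImage-class].
#' @slot mode `"memb"` or `"dict"`.
#' @slot general logical: allow general-mask queries regardless of policy.
#' @slot klcp logical vector (length 0 when not built): bit t is 1 iff the
#'   suffixes of rank t and t+1 share a common prefix of length >= k-1.
#' @slot state environment holding the mutable strand counter.
#' @seealso [buildIndex()], [kmerMember()], [kmerLookup()], [streamQuery()]
#' @exportClass MBWTIndex
setClass("MBWTIndex",
  representation(image = "MBWTImage", mode = "character", general = "logical",
                 klcp = "logical", state = "environment"))

setValidity("MBWTIndex", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("memb", "dict")) msg <- c(msg, "mode must be 'memb' or 'dict'")
  needed <- if (identical(object@mode, "memb")) "max-one" else "min-one"
  if (!object@general && !identical(object@image@policy, needed))
    msg <- c(msg, sprintf("mode '%s' requires a %s mask (or general-mask opt-in)",
                          object@mode, needed))
  if (length(object@klcp) > 0 && length(object@klcp) != length(object@image@codes))
    msg <- c(msg, "kLCP length must match the image")
  if (length(msg)) msg else TRUE
})

# Saturating strand predictor: a small signed counter bounded at +/-7 that
# remembers on which strand recent k-mers were found.
#' StrandPredictor: saturating strand counter
#'
#' A bounded signed counter (saturation 7) predicting whether the next
#' query k-mer is more likely found forward or reverse-complemented in the
#' superstring. Counter >= 0 predicts the forward strand.
#'
#' @slot counter integer in `[-saturation, saturation]`.
#' @slot saturation integer bound, fixed at 7.
#' @seealso [strandPredictor()], [predictStrand()], [updatePredictor()]
#' @exportClass StrandPredictor
setClass("StrandPredictor",
  representation(counter = "integer", saturation = "integer"))

setValidity("StrandPredictor", function(object) {
  if (abs(object@counter) > object@saturation) "counter exceeds saturation" else TRUE
})

#' KLCP: thresholded longest-common-prefix bit vector
#'
#' Bit t is 1 iff the suffixes of rank t and t+1 (in suffix-array order over
#' S plus sentinel) share a common prefix of length at least k-1; the last
#' bit is 0. Enables O(1)-amortized streamed queries.
#'
#' @slot bits logical vector of length `nchar(S) + 1`.
#' @slot k integer k-mer length.
#' @seealso [buildKLCP()], [extendToPrefixInterval()], [streamQuery()]
#' @exportClass KLCP
setClass("KLCP", representation(bits = "logical", k = "integer"))

setValidity("KLCP", function(object) {
  n <- length(object@bits)
  if (n > 0 && object@bits[n]) return("the last kLCP bit must be 0")
  TRUE
})

#' StreamResult: per-position answers and telemetry of a streamed query
#'
#' @slot op `"member"` or `"lookup"`.
#' @slot answers integer vector aligned to k-mer starts of the query text
#'   (0/1 for member, hash or -1 for lookup).
#' @slot telemetry list with counts of full backward searches, kLCP
#'   extensions, blocks and retried positions.
#' @seealso [streamQuery()], [streamAnswers()], [telemetry()]
#' @exportClass StreamResult
setClass("StreamResult",
  representation(op = "character", answers = "integer", telemetry = "list"))
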