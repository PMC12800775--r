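# Masked Burrows-Wheeler Transform: suffix array, (S', M') image, inversion,
# and the analytic mask-entropy term of the space accounting.

#' Suffix array of a superstring
#'
#' Sorts the suffixes of `S` plus a terminal sentinel `$` (sentinel smaller
#' than every base, character order $ < A < C < G < T). Construction uses
#' prefix doubling (worst-case safe); the naive quadratic sort is kept as a
#' test oracle only.
#'
#' @param S string over \{A,C,G,T\}.
#' @return a [SuffixArray-class] with 0-based positions.
#' @examples
#' saOrder(buildSuffixArray("ACGT"))  # 4 0 1 2 3
#' @export
buildSuffixArray <- function(S) {
  S <- toupper(as.character(S))
  stopifnot(length(S) == 1L)
  assert_dna(S, "superstring")
  new("SuffixArray", s = S, sa = cpp_suffix_array(S))
}

#' @describeIn accessors 0-based suffix order of a `SuffixArray`.
#' @export
setMethod("saOrder", "SuffixArray", function(x) x@sa)
#' @describeIn accessors the underlying string of a `SuffixArray` (without
#'   the sentinel).
#' @export
setMethod("superstring", "SuffixArray", function(x) x@s)

setMethod("show", "SuffixArray", function(object) {
  cat(sprintf("SuffixArray over %d characters + sentinel\n", nchar(object@s)))
})

.mbwt_image <- function(S, M, k, model, policy) {
  sa <- cpp_suffix_array(S)
  codes <- cpp_bwt_codes(S, sa)
  extmask <- c(M, FALSE)          # mask bit 0 for the sentinel position
  mprime <- extmask[sa + 1L]
  cnt <- tabulate(codes + 1L, nbins = 5L)
  counts <- c(0L, cumsum(cnt)[-5L])
  names(counts) <- MBWT_ALPHABET
  list(img = new("MBWTImage", codes = codes, mprime = mprime, counts = counts,
                 k = as.integer(k), model = model, policy = policy,
                 support = new.env(parent = emptyenv())),
       sa = sa)
}

#' Masked Burrows-Wheeler Transform of a masked superstring
#'
#' Computes the BWT `S'` of S plus sentinel (`S'[i] = text[sa[i] - 1 mod n]`)
#' together with the SA-transformed mask `M'[i] = M[sa[i]]` (the sentinel
#' position carries an appended 0). This direct form equals the
#' rotate-left-by-one, glue, BWT, unzip construction (see [mbwtCyclic()]);
#' the equivalence is exercised in the test suite.
#'
#' @param ms a [MaskedSuperstring-class].
#' @return an [MBWTImage-class].
#' @examples
#' img <- computeMBWT(maskedSuperstring("ACGT", "1100", k = 3))
#' bwtString(img)  # "T$ACG"
#' @export
computeMBWT <- function(ms) {
  stopifnot(is(ms, "MaskedSuperstring"))
  .mbwt_image(ms@S, ms@M, ms@k, ms@model, ms@policy)$img
}

#' Invert a Masked Burrows-Wheeler Transform
#'
#' Standard LF-mapping inversion extended to the mask: the LF walk from the
#' sentinel reconstructs S right to left, and each emitted character's mask
#' bit is read from `M'` at the SA rank of the suffix starting at that text
#' position. `invertMBWT(computeMBWT(ms))` recovers `ms` exactly.
#'
#' @param img an [MBWTImage-class].
#' @return a [MaskedSuperstring-class].
#' @export
invertMBWT <- function(img) {
  stopifnot(is(img, "MBWTImage"))
  res <- cpp_bwt_invert(img@codes)
  M <- if (length(res$rank_at) > 0) img@mprime[res$rank_at + 1L] else logical(0)
  new("MaskedSuperstring", S = res$text, M = M, k = img@k,
      model = img@model, policy = img@policy)
}

#' Rotate-and-glue MBWT construction under the cyclic convention
#'
#' The alternative construction of the SA-transformed mask: rotate the mask
#' one position to the left, glue mask symbols to superstring symbols, take
#' the BWT of the glued string comparing only superstring symbols, and
#' unzip. Works on sentinel-free strings under the cyclic-rotation
#' convention and therefore requires all rotations of `S` to be distinct
#' (i.e. `S` primitive). Retained to validate the direct definition used by
#' [computeMBWT()].
#'
#' @param S string over \{A,C,G,T\} with distinct rotations.
#' @param M mask (logical or bit string) of the same length.
#' @return list with elements `sprime` (string) and `mprime` (logical).
#' @export
mbwtCyclic <- function(S, M) {
  S <- toupper(as.character(S))
  assert_dna(S, "superstring")
  M <- as_mask_bits(M)
  n <- nchar(S)
  if (length(M) != n) stop("mask length must equal superstring length")
  if (n == 0) return(list(sprime = "", mprime = logical(0)))
  rots <- substring(strrep(S, 2L), 1:n, 1:n + n - 1L)
  if (anyDuplicated(rots))
    stop("cyclic MBWT requires a primitive string (all rotations distinct)")
  Mrot <- c(M[-1L], M[1L])                       # RotateToLeft(M, 1)
  ord <- order(rots, method = "radix")           # sort by S symbols only
  chars <- strsplit(S, "", fixed = TRUE)[[1]]
  last <- ((ord - 1L) - 1L) %% n + 1L            # last column position of each rotation
  list(sprime = paste(chars[last], collapse = ""), mprime = Mrot[last])
}

#' Mask entropy term of the index space bound
#'
#' `log2(choose(n, ones))` computed via log-gamma, the zeroth-order entropy
#' of a mask with `ones` set bits among `n`: the mask term of the analytic
#' space bound `2|S| + log2 C(|S|, |M|_1) + o(|S|)` bits.
#'
#' @param n mask length.
#' @param ones number of set bits, `0 <= ones <= n`.
#' @return numeric, in bits.
#' @examples
#' maskEntropyBits(4, 2)  # log2(6)
#' @export
maskEntropyBits <- function(n, ones) {
  if (any(ones > n) || any(ones < 0) || any(n < 0))
    stop("require 0 <= ones <= n")
  lchoose(n, ones) / log(2)
}

#' Rank over an MBWT image
#'
#' `mbwtRank(img, symbol, i)` counts occurrences of `symbol` among the first
#' `i` positions (0-based prefix) of `S'` (symbols `"$"`, `"A"`, ..., `"T"`)
#' or of `M'` (symbols `"0"`/`"1"`).
#'
#' @param img an [MBWTImage-class].
#' @param symbol one of `"$" "A" "C" "G" "T" "0" "1"`.
#' @param i prefix length, `0 <= i <= n`.
#' @return integer count.
#' @export
mbwtRank <- function(img, symbol, i) {
  stopifnot(is(img, "MBWTImage"))
  n <- length(img@codes)
  if (any(i < 0) || any(i > n)) stop("rank index out of range")
  sup <- .image_support(img)
  if (symbol %in% MBWT_ALPHABET) {
    code <- match(symbol, MBWT_ALPHABET) - 1L
    return(sup$occ[i + 1L, code + 1L])
  }
  if (symbol == "1") return(sup$m1[i + 1L])
  if (symbol == "0") return(as.integer(i) - sup$m1[i + 1L])
  stop("unknown symbol: ", symbol)
}

#' Select over an MBWT image
#'
#' `mbwtSelect(img, symbol, r)` returns the 0-based position of the r-th
#' (0-based) occurrence of `symbol` in `S'` or `M'`; the dual of
#' [mbwtRank()]: `mbwtRank(img, c, mbwtSelect(img, c, r)) == r`.
#'
#' @inheritParams mbwtRank
#' @param r 0-based occurrence rank.
#' @return integer position.
#' @export
mbwtSelect <- function(img, symbol, r) {
  stopifnot(is(img, "MBWTImage"))
  sup <- .image_support(img)
  pos <- if (symbol %in% MBWT_ALPHABET) {
    sup$selc[[match(symbol, MBWT_ALPHABET)]]
  } else if (symbol == "1") {
    sup$sel1
  } else if (symbol == "0") {
    sup$sel0
  } else stop("unknown symbol: ", symbol)
  if (any(r < 0) || any(r >= length(pos))) stop("select rank out of range")
  pos[r + 1L]
}

# Occurrence tables and select position lists, cached in the image's support
# environment on first use.
.image_support <- function(img) {
  env <- img@support
  if (is.null(env$occ)) {
    codes <- img@codes
    n <- length(codes)
    occ <- matrix(0L, nrow = n + 1L, ncol = 5L)
    for (c in 0:4) occ[, c + 1L] <- c(0L, cumsum(codes == c))
    env$occ <- occ
    env$m1 <- c(0L, cumsum(as.integer(img@mprime)))
    env$selc <- lapply(0:4, function(c) which(codes == c) - 1L)
    env$sel1 <- which(img@mprime) - 1L
    env$sel0 <- which(!img@mprime) - 1L
  }
  env
}

#' @describeIn accessors k-mer length of an `MBWTImage`.
#' @export
setMethod("kmerLength", "MBWTImage", function(x) x@k)
#' @describeIn accessors strand model of an `MBWTImage`.
#' @export
setMethod("strandModel", "MBWTImage", function(x) x@model)
#' @describeIn accessors mask policy of an `MBWTImage`.
#' @export
setMethod("maskPolicy", "MBWTImage", function(x) x@policy)
#' @describeIn accessors the BWT string S' (with sentinel `$`).
#' @export
setMethod("bwtString", "MBWTImage", function(x)
  paste(MBWT_ALPHABET[x@codes + 1L], collapse = ""))
#' @describeIn accessors the SA-transformed mask M' as a logical vector.
#' @export
setMethod("saMask", "MBWTImage", function(x) x@mprime)
#' @describeIn accessors named counts table: characters strictly smaller
#'   than each symbol.
#' @export
setMethod("charCounts", "MBWTImage", function(x) x@counts)

setMethod("show", "MBWTImage", function(object) {
  n <- length(object@codes)
  cat(sprintf("MBWTImage: n = %d (incl. sentinel), %d mask 1s, k = %d (%s, %s)\n",
              n, sum(object@mprime), object@k, object@model, object@policy))
  if (n <= 60) {
    cat("  S' = ", bwtString(object), "\n  M' = ",
        mask_to_string(object@mprime), "\n", sep = "")
  }
})
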