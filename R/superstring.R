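#' Construct a MaskedSuperstring
#'
#' @param S superstring over \{A,C,G,T\} (upcased on input for convenience;
#'   use [readMaskedSuperstring()] for the case-encoded interchange format).
#' @param M mask: logical/0-1 vector or a bit string like `"1100"`.
#' @param k k-mer length.
#' @param model strand model.
#' @param policy mask policy; `"unoptimized"` unless the caller guarantees
#'   min-one or max-one form (see [applyMaskPolicy()]).
#' @return a [MaskedSuperstring-class].
#' @examples
#' maskedSuperstring("ACGT", "1100", k = 3, model = "unidirectional")
#' @export
maskedSuperstring <- function(S, M, k,
                              model = c("unidirectional", "bidirectional"),
                              policy = c("unoptimized", "min-one", "max-one")) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  S <- toupper(as.character(S))
  new("MaskedSuperstring", S = S, M = as_mask_bits(M), k = as.integer(k),
      model = model, policy = policy)
}

#' Approximately shortest masked superstring via global greedy merging
#'
#' Builds a superstring containing every k-mer of the set as a substring (in
#' either orientation under the bidirectional model) by greedily merging
#' strings in order of decreasing suffix-prefix overlap length (k-1 down
#' to 0). Ties are broken by lexicographic order of the merged pair (then
#' orientation flags), self-merges and cycles are forbidden, and leftover
#' unmergeable strings are concatenated in lexicographic order, so the
#' construction is fully deterministic. Under the bidirectional model each
#' canonical k-mer is usable in either orientation and is placed exactly
#' once. The output mask is in min-one form. `nchar(S) <= k * |K|` always;
#' for spectrum-like sets (k-mers of a few long strings) the greedy
#' approximately rediscovers the chains, giving `nchar(S)` close to
#' `|K| + k - 1`.
#'
#' @param x a [KmerSet-class]. An empty set yields the empty masked
#'   superstring.
#' @return a [MaskedSuperstring-class] with min-one mask.
#' @examples
#' ms <- greedySuperstring(kmerSet(c("ACG", "CGT")))
#' superstring(ms)  # "ACGT"
#' @export
greedySuperstring <- function(x) {
  stopifnot(is(x, "KmerSet"))
  k <- kmerLength(x)
  model <- strandModel(x)
  if (length(x) == 0) {
    return(new("MaskedSuperstring", S = "", M = logical(0), k = k,
               model = model, policy = "min-one"))
  }
  bidir <- model == "bidirectional"
  S <- cpp_greedy_superstring(kmers(x), k, bidir)
  M <- cpp_mask_policy(S, kmers(x), k, bidir, TRUE)
  new("MaskedSuperstring", S = S, M = M, k = k, model = model,
      policy = "min-one")
}

#' Masked superstring from a spectrum-preserving string set (SPSS)
#'
#' Concatenates the segments (simplitigs, unitigs, eulertigs, ...) with no
#' separators and masks the first `length - k + 1` positions of each segment
#' with 1; windows spanning segment junctions are ghosts and carry 0. The
#' represented set is the union of the segments' k-mers.
#'
#' @param segments character vector of DNA strings, each of length >= k.
#' @param k k-mer length.
#' @param model strand model.
#' @return a [MaskedSuperstring-class] (policy `"unoptimized"`: duplicate
#'   k-mers across segments may be marked more than once).
#' @examples
#' ms <- spssSuperstring(c("ACG", "TTT"), k = 3)
#' mask_string <- paste(as.integer(maskBits(ms)), collapse = "")  # "100100"
#' @export
spssSuperstring <- function(segments, k,
                            model = c("unidirectional", "bidirectional")) {
  model <- match.arg(model)
  k <- as.integer(k)
  segments <- toupper(as.character(segments))
  if (length(segments) == 0) {
    return(new("MaskedSuperstring", S = "", M = logical(0), k = k,
               model = model, policy = "unoptimized"))
  }
  assert_dna(segments, "SPSS segment")
  if (any(nchar(segments) < k))
    stop("every SPSS segment must have length >= k")
  lens <- nchar(segments)
  M <- unlist(lapply(lens, function(l) c(rep(TRUE, l - k + 1L), rep(FALSE, k - 1L))))
  new("MaskedSuperstring", S = paste(segments, collapse = ""), M = M,
      k = k, model = model, policy = "unoptimized")
}

#' Re-optimize the mask of a masked superstring
#'
#' Recomputes the mask by a single left-to-right scan, keeping the
#' superstring byte-identical and the represented set unchanged. min-one
#' marks the leftmost occurrence of each represented k-mer (deterministic
#' and scan-friendly); max-one marks every position whose (canonical, under
#' the bidirectional model) k-mer is represented, which makes all mask bits
#' inside one SA interval agree -- the property membership queries rely on.
#'
#' @param ms a [MaskedSuperstring-class].
#' @param policy target policy, `"min-one"` or `"max-one"`.
#' @return a [MaskedSuperstring-class].
#' @export
applyMaskPolicy <- function(ms, policy = c("min-one", "max-one")) {
  stopifnot(is(ms, "MaskedSuperstring"))
  policy <- match.arg(policy)
  bidir <- ms@model == "bidirectional"
  K <- cpp_represented(ms@S, ms@M, ms@k, bidir)
  M <- cpp_mask_policy(ms@S, K, ms@k, bidir, policy == "min-one")
  new("MaskedSuperstring", S = ms@S, M = M, k = ms@k, model = ms@model,
      policy = policy)
}

#' @rdname representedSet
#' @export
setMethod("representedSet", "MaskedSuperstring", function(x) {
  bidir <- x@model == "bidirectional"
  new("KmerSet", k = x@k, model = x@model,
      kmers = as.character(cpp_represented(x@S, x@M, x@k, bidir)))
})

#' @describeIn accessors k-mer length of a `MaskedSuperstring`.
#' @export
setMethod("kmerLength", "MaskedSuperstring", function(x) x@k)
#' @describeIn accessors strand model of a `MaskedSuperstring`.
#' @export
setMethod("strandModel", "MaskedSuperstring", function(x) x@model)
#' @describeIn accessors the superstring S.
#' @export
setMethod("superstring", "MaskedSuperstring", function(x) x@S)
#' @describeIn accessors the mask M as a logical vector.
#' @export
setMethod("maskBits", "MaskedSuperstring", function(x) x@M)
#' @describeIn accessors the mask policy.
#' @export
setMethod("maskPolicy", "MaskedSuperstring", function(x) x@policy)

setMethod("show", "MaskedSuperstring", function(object) {
  n <- nchar(object@S)
  cat(sprintf("MaskedSuperstring: |S| = %d, %d mask 1s, k = %d (%s, %s)\n",
              n, sum(object@M), object@k, object@model, object@policy))
  if (n > 0 && n <= 60) {
    cat("  ", object@S, "\n  ", mask_to_string(object@M), "\n", sep = "")
  }
})
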