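# Accessor generics. Slot access from user code is discouraged; these are the
# stable surface.

#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))
#' @rdname accessors
#' @export
setGeneric("strandModel", function(x) standardGeneric("strandModel"))
#' @rdname accessors
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))
#' @rdname accessors
#' @export
setGeneric("superstring", function(x) standardGeneric("superstring"))
#' @rdname accessors
#' @export
setGeneric("maskBits", function(x) standardGeneric("maskBits"))
#' @rdname accessors
#' @export
setGeneric("maskPolicy", function(x) standardGeneric("maskPolicy"))
#' @rdname accessors
#' @export
setGeneric("saOrder", function(x) standardGeneric("saOrder"))
#' @rdname accessors
#' @export
setGeneric("bwtString", function(x) standardGeneric("bwtString"))
#' @rdname accessors
#' @export
setGeneric("saMask", function(x) standardGeneric("saMask"))
#' @rdname accessors
#' @export
setGeneric("charCounts", function(x) standardGeneric("charCounts"))
#' @rdname accessors
#' @export
setGeneric("indexMode", function(x) standardGeneric("indexMode"))
#' @rdname accessors
#' @export
setGeneric("klcpBits", function(x) standardGeneric("klcpBits"))
#' @rdname accessors
#' @export
setGeneric("streamAnswers", function(x) standardGeneric("streamAnswers"))
#' @rdname accessors
#' @export
setGeneric("telemetry", function(x) standardGeneric("telemetry"))

#' Decode the k-mer set represented by a masked superstring
#'
#' Returns the set of k-mers (canonicalized under the bidirectional model)
#' that have at least one occurrence with mask bit 1. This is the decode
#' oracle: for any mask policy, `representedSet()` recovers exactly the
#' source k-mer set.
#'
#' @param x a [MaskedSuperstring-class].
#' @return a [KmerSet-class].
#' @examples
#' ms <- maskedSuperstring("ACGT", "1100", k = 3, model = "unidirectional")
#' kmers(representedSet(ms))
#' @export
setGeneric("representedSet", function(x) standardGeneric("representedSet"))
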