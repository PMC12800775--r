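#' Reverse complement of DNA strings
#'
#' Reverses each string and complements the bases (A<->T, C<->G). Involutive:
#' `revComp(revComp(x)) == x`.
#'
#' @param x character vector over \{A,C,G,T\} (empty strings allowed).
#' @return character vector of the same length.
#' @examples
#' revComp("ACG")   # "CGT"
#' revComp("AT")    # palindromic
#' @export
revComp <- function(x) {
  stopifnot(is.character(x))
  assert_dna(x, "DNA string")
  cpp_revcomp(x)
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement (the k-mer itself when palindromic).
#' Under the bidirectional model a k-mer and its reverse complement are
#' considered the same object and the canonical form is the stored
#' representative, which makes dictionary hashes stable.
#'
#' @param x character vector of k-mers over \{A,C,G,T\}.
#' @return character vector of canonical k-mers.
#' @examples
#' canonicalKmer("CGT")   # "ACG"
#' canonicalKmer("ACGT")  # self-reverse-complement palindrome
#' @export
canonicalKmer <- function(x) {
  stopifnot(is.character(x))
  assert_dna(x, "k-mer")
  cpp_canonical(x)
}

#' Construct a KmerSet
#'
#' Lower-case letters are upcased on ingestion. Under the bidirectional
#' model members are canonicalized; duplicates are dropped and the set is
#' stored sorted.
#'
#' @param kmers character vector of k-mers.
#' @param k k-mer length; inferred from `kmers` when missing.
#' @param model `"unidirectional"` or `"bidirectional"`.
#' @return a [KmerSet-class].
#' @examples
#' kmerSet(c("ACG", "CGT"), model = "bidirectional")  # collapses to {ACG}
#' @export
kmerSet <- function(kmers, k = NULL,
                    model = c("unidirectional", "bidirectional")) {
  model <- match.arg(model)
  kmers <- toupper(as.character(kmers))
  if (is.null(k)) {
    if (length(kmers) == 0) stop("k must be given for an empty set")
    k <- nchar(kmers[1])
  }
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (length(kmers) > 0) {
    if (!all(nchar(kmers) == k)) stop("all k-mers must have length k")
    assert_dna(kmers, "k-mer")
    if (model == "bidirectional") kmers <- cpp_canonical(kmers)
    kmers <- sort(unique(kmers), method = "radix")
  }
  new("KmerSet", k = k, model = model, kmers = kmers)
}

#' Extract the k-mer set of a collection of sequences
#'
#' All length-k windows of all sequences, canonicalized under the
#' bidirectional model. Windows containing any non-ACGT letter (N, IUPAC
#' ambiguity codes, ...) are skipped, mirroring common k-mer tooling;
#' set `strict = TRUE` to reject such sequences outright. Sequences shorter
#' than k contribute nothing. Lower-case input is upcased.
#'
#' @param sequences character vector of DNA sequences.
#' @param k k-mer length (>= 2).
#' @param model strand model.
#' @param strict reject sequences with non-ACGT letters instead of skipping
#'   the affected windows.
#' @return a [KmerSet-class].
#' @examples
#' kmers(extractKmers("ACGT", k = 3))                            # ACG, CGT
#' kmers(extractKmers("ACGT", k = 3, model = "bidirectional"))   # ACG
#' @export
extractKmers <- function(sequences, k,
                         model = c("unidirectional", "bidirectional"),
                         strict = FALSE) {
  model <- match.arg(model)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  sequences <- toupper(as.character(sequences))
  if (strict) assert_dna(sequences, "sequence")
  km <- cpp_extract_kmers(sequences, k, model == "bidirectional")
  new("KmerSet", k = k, model = model, kmers = km)
}

#' Uniformly subsample a k-mer set
#'
#' Deterministic given `seed`. By default each k-mer is kept independently
#' with probability `fraction` (Bernoulli sampling); with `exact = TRUE`
#' exactly `round(fraction * |K|)` k-mers are kept (hypergeometric variant).
#' k and the strand model are preserved.
#'
#' @param x a [KmerSet-class].
#' @param fraction keep probability in `[0, 1]`.
#' @param seed integer seed.
#' @param exact force the subsample cardinality to `round(fraction * |K|)`.
#' @return a [KmerSet-class].
#' @export
subsampleKmers <- function(x, fraction, seed, exact = FALSE) {
  stopifnot(is(x, "KmerSet"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a single number in [0, 1]")
  km <- kmers(x)
  n <- length(km)
  keep <- with_seed(seed, {
    if (exact) {
      m <- round(fraction * n)
      sort(sample.int(n, m))
    } else {
      which(runif(n) < fraction)
    }
  })
  new("KmerSet", k = kmerLength(x), model = strandModel(x), kmers = km[keep])
}

#' @describeIn accessors k-mer length of a `KmerSet`.
#' @export
setMethod("kmerLength", "KmerSet", function(x) x@k)
#' @describeIn accessors strand model of a `KmerSet`.
#' @export
setMethod("strandModel", "KmerSet", function(x) x@model)
#' @describeIn accessors the sorted k-mers of a `KmerSet`.
#' @export
setMethod("kmers", "KmerSet", function(x) x@kmers)

#' @export
setMethod("length", "KmerSet", function(x) length(x@kmers))

setMethod("show", "KmerSet", function(object) {
  cat(sprintf("KmerSet: %d distinct %d-mers (%s model)\n",
              length(object@kmers), object@k, object@model))
  if (length(object@kmers) > 0) {
    shown <- utils::head(object@kmers, 5L)
    cat("  ", paste(shown, collapse = " "),
        if (length(object@kmers) > 5L) "..." else "", "\n")
  }
})
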