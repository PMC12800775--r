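# Synthetic fixture generator: random genomes, mutated pangenomes, uniform
# random k-mer sets (overlap-free worst case), and subsampled variants. All
# outputs are deterministic given the seed.

#' Generate synthetic sequence / k-mer-set fixtures
#'
#' * `random_genome` -- one uniform ACGT string of length `L`: a
#'   spectrum-like k-mer set generated by a single long string.
#' * `pangenome` -- `g` mutants of one random base genome with i.i.d.
#'   substitutions at per-base rate `mu`, emulating high-diversity
#'   pangenomic sets (many short overlap-breaking differences).
#' * `random_kmers` -- `n` uniform random k-mers, emulating overlap-free
#'   sets such as heavily sketched data: the worst case for de-Bruijn-graph
#'   based methods and the regime where superstring indexing keeps its
#'   guarantees.
#' * `subsampled` -- any of the above passed through [subsampleKmers()]
#'   with keep fraction `fraction`.
#'
#' @param kind fixture kind, see above.
#' @param k k-mer length.
#' @param seed integer seed; equal seeds give identical fixtures.
#' @param model strand model of the extracted k-mer set.
#' @param L genome length (`random_genome`, `pangenome`).
#' @param g number of genomes in the pangenome.
#' @param mu per-base substitution rate in `[0, 1]`.
#' @param n number of random k-mers.
#' @param fraction keep fraction for `subsampled`.
#' @param base kind subsampled from (`"random_genome"`, `"pangenome"` or
#'   `"random_kmers"`).
#' @return list with elements `sequences` (character vector, possibly
#'   empty for `random_kmers`) and `kmers` (a [KmerSet-class]).
#' @examples
#' fx <- generateFixture("random_genome", k = 11, seed = 1, L = 500)
#' length(fx$kmers)
#' @export
generateFixture <- function(kind = c("random_genome", "pangenome",
                                     "random_kmers", "subsampled"),
                            k, seed,
                            model = c("bidirectional", "unidirectional"),
                            L = 10000L, g = 4L, mu = 0.01, n = 1000L,
                            fraction = 0.1, base = "random_genome") {
  kind <- match.arg(kind)
  model <- match.arg(model)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (L < 1 || g < 1 || n < 1 || mu < 0 || mu > 1)
    stop("invalid fixture parameters")

  rand_seq <- function(len) paste(sample(DNA_BASES, len, replace = TRUE),
                                  collapse = "")
  mutate <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < mu)
    if (length(hit) > 0) {
      repl <- vapply(chars[hit], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
      chars[hit] <- repl
    }
    paste(chars, collapse = "")
  }

  if (kind == "subsampled") {
    base <- match.arg(base, c("random_genome", "pangenome", "random_kmers"))
    inner <- generateFixture(base, k = k, seed = seed, model = model,
                             L = L, g = g, mu = mu, n = n)
    ks <- subsampleKmers(inner$kmers, fraction, seed = seed + 1L)
    return(list(sequences = inner$sequences, kmers = ks))
  }

  with_seed(seed, {
    if (kind == "random_genome") {
      seqs <- rand_seq(L)
      list(sequences = seqs, kmers = extractKmers(seqs, k, model))
    } else if (kind == "pangenome") {
      ref <- rand_seq(L)
      seqs <- c(ref, vapply(seq_len(g - 1L), function(i) mutate(ref),
                            character(1)))
      list(sequences = seqs, kmers = extractKmers(seqs, k, model))
    } else {
      km <- vapply(seq_len(n), function(i) rand_seq(k), character(1))
      list(sequences = character(0), kmers = kmerSet(km, k = k, model = model))
    }
  })
}
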