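# Shared study-condition fixtures for the acceptance suite: 20 k-mer sets
# spanning k in {5, 7, 11, 15, 31}, random genomes (L <= 50 kb), mutated
# pangenomes (g <= 8), uniform random k-mer sets (n <= 5000) and 10%
# subsampled variants, across both strand models. Masked superstrings are
# computed once and cached for reuse across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture_specs <- function() {
  list(
    list(name = "genome-k5-uni",      kind = "random_genome", k = 5L,  seed = 101L, model = "unidirectional", L = 5000L),
    list(name = "pangenome-k5-bi",    kind = "pangenome",     k = 5L,  seed = 102L, model = "bidirectional",  L = 2000L, g = 6L, mu = 0.02),
    list(name = "randkmers-k5-bi",    kind = "random_kmers",  k = 5L,  seed = 103L, model = "bidirectional",  n = 300L),
    list(name = "subsampled-k5-bi",   kind = "subsampled",    k = 5L,  seed = 104L, model = "bidirectional",  L = 5000L, base = "random_genome", fraction = 0.1),
    list(name = "genome-k7-bi",       kind = "random_genome", k = 7L,  seed = 111L, model = "bidirectional",  L = 10000L),
    list(name = "pangenome-k7-uni",   kind = "pangenome",     k = 7L,  seed = 112L, model = "unidirectional", L = 3000L, g = 8L, mu = 0.02),
    list(name = "randkmers-k7-uni",   kind = "random_kmers",  k = 7L,  seed = 113L, model = "unidirectional", n = 2000L),
    list(name = "subsampled-k7-uni",  kind = "subsampled",    k = 7L,  seed = 114L, model = "unidirectional", L = 10000L, base = "random_genome", fraction = 0.1),
    list(name = "genome-k11-uni",     kind = "random_genome", k = 11L, seed = 121L, model = "unidirectional", L = 20000L),
    list(name = "pangenome-k11-bi",   kind = "pangenome",     k = 11L, seed = 122L, model = "bidirectional",  L = 5000L, g = 6L, mu = 0.02),
    list(name = "randkmers-k11-bi",   kind = "random_kmers",  k = 11L, seed = 123L, model = "bidirectional",  n = 5000L),
    list(name = "subsampled-k11-bi",  kind = "subsampled",    k = 11L, seed = 124L, model = "bidirectional",  L = 5000L, g = 6L, mu = 0.02, base = "pangenome", fraction = 0.1),
    list(name = "genome-k15-bi",      kind = "random_genome", k = 15L, seed = 131L, model = "bidirectional",  L = 30000L),
    list(name = "pangenome-k15-uni",  kind = "pangenome",     k = 15L, seed = 132L, model = "unidirectional", L = 8000L, g = 8L, mu = 0.02),
    list(name = "randkmers-k15-uni",  kind = "random_kmers",  k = 15L, seed = 133L, model = "unidirectional", n = 5000L),
    list(name = "subsampled-k15-uni", kind = "subsampled",    k = 15L, seed = 134L, model = "unidirectional", n = 5000L, base = "random_kmers", fraction = 0.1),
    list(name = "genome-k31-bi",      kind = "random_genome", k = 31L, seed = 141L, model = "bidirectional",  L = 50000L),
    list(name = "pangenome-k31-uni",  kind = "pangenome",     k = 31L, seed = 142L, model = "unidirectional", L = 10000L, g = 8L, mu = 0.02),
    list(name = "randkmers-k31-bi",   kind = "random_kmers",  k = 31L, seed = 143L, model = "bidirectional",  n = 5000L),
    list(name = "subsampled-k31-uni", kind = "subsampled",    k = 31L, seed = 144L, model = "unidirectional", L = 50000L, base = "random_genome", fraction = 0.1)
  )
}

acceptance_fixtures <- function() {
  if (!is.null(.fixture_env$fixtures)) return(.fixture_env$fixtures)
  fx <- lapply(fixture_specs(), function(sp) {
    args <- sp[setdiff(names(sp), c("name", "kind"))]
    gen <- do.call(generateFixture, c(list(kind = sp$kind), args))
    ms <- greedySuperstring(gen$kmers)   # min-one mask
    list(name = sp$name, kind = sp$kind, k = sp$k, model = sp$model,
         ks = gen$kmers, seqs = gen$sequences, ms = ms)
  })
  names(fx) <- vapply(fx, `[[`, "", "name")
  .fixture_env$fixtures <- fx
  fx
}
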