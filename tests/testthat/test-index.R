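micro_memb <- function() {
  buildIndex(maskedSuperstring("ACGT", "1100", 3, policy = "max-one"), "memb")
}
micro_dict <- function() {
  buildIndex(maskedSuperstring("ACGT", "1100", 3, policy = "min-one"), "dict")
}

test_that("backward search walks the hand-derived FM steps", {
  idx <- micro_memb()
  expect_identical(backwardSearch(idx, "ACG"), c(1L, 2L))  # G:[3,4) C:[2,3) A:[1,2)
  expect_identical(backwardSearch(idx, "CCC"), c(0L, 0L))
  expect_identical(backwardSearch(idx, ""), c(0L, 5L))

  set.seed(51)
  S <- rand_dna(300)
  ms <- maskedSuperstring(S, rep(FALSE, 300), 5, policy = "max-one")
  idx2 <- buildIndex(ms, "memb")
  for (pat in c(windows_of(S, 5)[sample(296, 20)], rand_kmers(20, 5)))
    expect_identical(backwardSearch(idx2, pat), naive_interval(S, pat))
})

test_that("membership matches the hash-set oracle, including strand logic", {
  idx <- micro_memb()
  expect_true(kmerMember(idx, "ACG"))
  expect_false(kmerMember(idx, "AAA"))
  expect_error(kmerMember(idx, "ACGT"), "length k")

  # bidirectional: stored orientation found through the reverse strand
  bi <- indexKmerSet(kmerSet("ACG", model = "bidirectional"), "memb")
  expect_true(kmerMember(bi, "CGT"))
  expect_true(kmerMember(bi, "ACG"))

  # empty index answers false to everything
  e <- buildIndex(applyMaskPolicy(greedySuperstring(kmerSet(character(0), k = 3)),
                                  "max-one"), "memb")
  expect_false(any(kmerMember(e, c("AAA", "ACG", "TTT"))))

  # exhaustive equivalence at small k
  fx <- generateFixture("pangenome", k = 4, seed = 52, L = 300, g = 3, mu = 0.05)
  idx4 <- indexKmerSet(fx$kmers, "memb")
  Q <- all_kmers(4)
  expect_identical(kmerMember(idx4, Q), oracle_member(Q, fx$kmers))
})

test_that("general-mask membership counts marked occurrences in the interval", {
  ms <- maskedSuperstring("ACGT", "1000", 3)   # unoptimized: CGT unmarked
  idx <- buildIndex(ms, "memb", generalMask = TRUE)
  expect_true(kmerMemberGeneral(idx, "ACG"))
  expect_false(kmerMemberGeneral(idx, "CGT"))  # interval exists, no 1
  expect_false(kmerMemberGeneral(idx, "AAA"))

  # agrees with the max-one fast path on max-one indexes
  fx <- generateFixture("random_genome", k = 6, seed = 53, L = 1500)
  idx6 <- buildIndex(applyMaskPolicy(greedySuperstring(fx$kmers), "max-one"),
                     "memb", generalMask = TRUE)
  Q <- c(kmers(fx$kmers), rand_kmers(500, 6))
  expect_identical(kmerMemberGeneral(idx6, Q), kmerMember(idx6, Q))
})

test_that("lookup is a minimal perfect hash with rejection", {
  d <- micro_dict()
  expect_identical(kmerLookup(d, c("ACG", "CGT", "TTT")), c(0L, 1L, -1L))

  for (model in c("unidirectional", "bidirectional")) {
    fx <- generateFixture("pangenome", k = 9, seed = 54, L = 800, g = 4,
                          mu = 0.03, model = model)
    d9 <- indexKmerSet(fx$kmers, "dict")
    h <- kmerLookup(d9, kmers(fx$kmers))
    expect_identical(sort(h), 0:(length(fx$kmers) - 1L))   # bijection
    absent <- setdiff(rand_kmers(2000, 9),
                      c(kmers(fx$kmers), revComp(kmers(fx$kmers))))
    expect_true(all(kmerLookup(d9, absent) == -1L))
  }
})

test_that("access inverts lookup and reports out-of-range hashes", {
  d <- micro_dict()
  expect_identical(kmerAccess(d, 0), "ACG")   # psi-walk rows 1 -> 2 -> 3
  expect_identical(kmerAccess(d, 1), "CGT")
  expect_error(kmerAccess(d, 2), "out of range")
  expect_error(kmerAccess(d, -1), "out of range")

  fx <- generateFixture("random_genome", k = 9, seed = 55, L = 3000,
                        model = "bidirectional")
  d9 <- indexKmerSet(fx$kmers, "dict")
  K <- kmers(fx$kmers)
  h <- kmerLookup(d9, K)
  back <- kmerAccess(d9, h)
  expect_true(all(back == K | revComp(back) == K))   # access o lookup
  expect_identical(kmerLookup(d9, kmerAccess(d9, 0:(length(K) - 1L))),
                   0:(length(K) - 1L))               # lookup o access
})

test_that("max-one SA intervals are bit-uniform across every window of S", {
  fx <- generateFixture("pangenome", k = 5, seed = 56, L = 400, g = 3, mu = 0.05)
  ms <- applyMaskPolicy(greedySuperstring(fx$kmers), "max-one")
  idx <- buildIndex(ms, "memb")
  mp <- saMask(idx@image)
  for (w in unique(windows_of(superstring(ms), 5))) {
    iv <- backwardSearch(idx, w)
    expect_true(iv[1] < iv[2])
    expect_length(unique(mp[(iv[1] + 1):iv[2]]), 1L)
  }
})

test_that("the strand predictor changes search order, never answers", {
  fx <- generateFixture("pangenome", k = 7, seed = 57, L = 600, g = 4,
                        mu = 0.05, model = "bidirectional")
  Q <- c(kmers(fx$kmers), rand_kmers(1000, 7))
  memb <- indexKmerSet(fx$kmers, "memb")
  expect_identical(kmerMember(memb, Q, counter = 7L),
                   kmerMember(memb, Q, counter = -7L))
  dict <- indexKmerSet(fx$kmers, "dict")
  expect_identical(kmerLookup(dict, Q, counter = 7L),
                   kmerLookup(dict, Q, counter = -7L))

  # persistent counter saturates at +/-7 and moves toward observed strands
  expect_identical(predictStrand(strandPredictor(0L)), "forward")
  expect_identical(predictStrand(strandPredictor(-1L)), "reverse")
  p <- strandPredictor(6L)
  p <- updatePredictor(updatePredictor(p, "forward"), "forward")
  expect_identical(p@counter, 7L)
  idxc <- indexKmerSet(kmerSet("AAAAC", model = "bidirectional"), "memb")
  for (i in 1:10) kmerMember(idxc, "AAAAC")
  expect_lte(abs(idxc@state$counter), 7L)
})

test_that("mode/policy contracts are enforced at build time", {
  ms <- maskedSuperstring("ACGT", "1100", 3)    # unoptimized
  expect_error(buildIndex(ms, "memb"), "max-one")
  expect_error(buildIndex(ms, "dict"), "min-one")
  expect_s4_class(buildIndex(ms, "memb", generalMask = TRUE), "MBWTIndex")
  d <- micro_dict()
  expect_error(kmerMember(d, "ACG"), "memb")
  expect_error(kmerAccess(micro_memb(), 0), "dict")
})

test_that("space accounting reports the analytic terms and respects the bound", {
  idx <- micro_memb()
  rep2 <- spaceReport(idx, 2)
  expect_identical(rep2$superstring_bits, 8)
  expect_equal(rep2$mask_bits, log2(6))
  expect_equal(rep2$bits_per_kmer, (8 + log2(6)) / 2)
  expect_named(spaceReport(idx, 0),
               c("superstring_bits", "mask_bits", "total_bits", "overhead_bits"))

  set.seed(58)
  for (rep in 1:6) {
    k <- sample(c(5, 9, 13), 1)
    ks <- kmerSet(unique(rand_kmers(300, k)),
                  model = sample(c("unidirectional", "bidirectional"), 1))
    ms <- greedySuperstring(ks)
    i2 <- buildIndex(ms, "dict")
    sr <- spaceReport(i2, length(ks))
    slen <- nchar(superstring(ms))
    expect_lte(sr$superstring_bits + sr$mask_bits, 3 * slen)
    expect_equal(sr$total_bits, sr$superstring_bits + sr$mask_bits)
    expect_equal(sr$mask_bits, maskEntropyBits(slen, length(ks)))
  }
})
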