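test_that("greedy superstring reproduces forced merges on tiny sets", {
  ms <- greedySuperstring(kmerSet(c("ACG", "CGT"), model = "unidirectional"))
  expect_identical(superstring(ms), "ACGT")   # overlap-2 merge is forced
  expect_identical(maskBits(ms), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(maskPolicy(ms), "min-one")

  ms1 <- greedySuperstring(kmerSet("ACG", model = "bidirectional"))
  expect_identical(superstring(ms1), "ACG")
  expect_identical(maskBits(ms1), c(TRUE, FALSE, FALSE))

  ms0 <- greedySuperstring(kmerSet(character(0), k = 3))
  expect_identical(superstring(ms0), "")
  expect_length(maskBits(ms0), 0)
})

test_that("greedy superstring represents exactly the source set (round trip)", {
  set.seed(21)
  for (rep in 1:12) {
    k <- sample(3:15, 1)
    model <- sample(c("unidirectional", "bidirectional"), 1)
    ks <- kmerSet(unique(rand_kmers(sample(c(5, 40, 200), 1), k)), model = model)
    ms <- greedySuperstring(ks)
    expect_lte(nchar(superstring(ms)), k * length(ks))
    expect_identical(kmers(representedSet(ms)), kmers(ks))
    expect_identical(sum(maskBits(ms)), length(ks))  # min-one popcount
  }
})

test_that("greedy rediscovers the chain of a single-sequence spectrum", {
  # k-mers of one random sequence: the superstring should approximately
  # match the generating sequence length, both strand models.
  for (model in c("unidirectional", "bidirectional")) {
    fx <- generateFixture("random_genome", k = 13, seed = 22, L = 2000,
                          model = model)
    ms <- greedySuperstring(fx$kmers)
    expect_lte(nchar(superstring(ms)), 1.1 * (length(fx$kmers) + 13 - 1))
    expect_identical(kmers(representedSet(ms)), kmers(fx$kmers))
  }
})

test_that("SPSS conversion concatenates segments and masks junction ghosts", {
  ms <- spssSuperstring("ACGT", k = 3)
  expect_identical(superstring(ms), "ACGT")
  expect_identical(maskBits(ms), c(TRUE, TRUE, FALSE, FALSE))

  ms2 <- spssSuperstring(c("ACG", "TTT"), k = 3)
  expect_identical(superstring(ms2), "ACGTTT")
  expect_identical(paste(as.integer(maskBits(ms2)), collapse = ""), "100100")
  # junction windows CGT, GTT are ghosts
  expect_identical(kmers(representedSet(ms2)), c("ACG", "TTT"))

  expect_identical(superstring(spssSuperstring(character(0), k = 3)), "")
  expect_error(spssSuperstring(c("ACG", "GT"), k = 3), ">= k")
})

test_that("greedy never exceeds an overlap-free SPSS, which never exceeds k|K|", {
  # On a branch-free spectrum (no repeated (k-1)-mer) the generating
  # sequence is the unique chain and greedy must rediscover it exactly;
  # under heavy de-Bruijn-graph branching greedy has no dominance guarantee
  # over an arbitrary SPSS, so the comparison is made where it is provable.
  set.seed(23)
  done <- 0
  while (done < 5) {
    s <- rand_dna(500)
    k <- sample(8:12, 1)
    if (anyDuplicated(windows_of(s, k - 1))) next
    ks <- extractKmers(s, k, "unidirectional")
    spss <- spssSuperstring(s, k)   # the generating sequence is an SPSS
    expect_identical(kmers(representedSet(spss)), kmers(ks))
    g <- greedySuperstring(ks)
    expect_lte(nchar(superstring(g)), nchar(superstring(spss)))
    expect_lte(nchar(superstring(spss)), k * length(ks))
    done <- done + 1
  }

  # with branching, greedy still respects the k|K| bound and the round trip
  s <- rand_dna(500)
  ks4 <- extractKmers(s, 4, "unidirectional")
  g4 <- greedySuperstring(ks4)
  expect_lte(nchar(superstring(g4)), 4 * length(ks4))
  expect_identical(kmers(representedSet(g4)), kmers(ks4))
})

test_that("mask policies recompute marks without touching the superstring", {
  # ACG occurs at positions 0 and 3 of ACGACG
  ms <- spssSuperstring(c("ACG", "ACG"), k = 3)   # S = ACGACG
  K <- representedSet(ms)
  maxone <- applyMaskPolicy(ms, "max-one")
  minone <- applyMaskPolicy(ms, "min-one")
  expect_identical(superstring(maxone), superstring(ms))
  expect_identical(paste(as.integer(maskBits(maxone)), collapse = ""), "100100")
  expect_identical(paste(as.integer(maskBits(minone)), collapse = ""), "100000")
  expect_identical(kmers(representedSet(maxone)), kmers(K))
  expect_identical(kmers(representedSet(minone)), kmers(K))

  # S = ACGACG representing {ACG, CGA, GAC}: every window is a k-mer
  ms2 <- maskedSuperstring("ACGACG", "111000", k = 3)
  expect_identical(paste(as.integer(maskBits(applyMaskPolicy(ms2, "max-one"))),
                         collapse = ""), "111100")
  expect_identical(paste(as.integer(maskBits(applyMaskPolicy(ms2, "min-one"))),
                         collapse = ""), "111000")

  # unique occurrences: min-one == max-one
  ms3 <- maskedSuperstring("ACGT", "1100", k = 3)
  expect_identical(maskBits(applyMaskPolicy(ms3, "min-one")),
                   maskBits(applyMaskPolicy(ms3, "max-one")))
})

test_that("policy conversion is path-independent and popcounts obey the policy", {
  set.seed(24)
  for (rep in 1:8) {
    k <- sample(3:8, 1)
    model <- sample(c("unidirectional", "bidirectional"), 1)
    ks <- kmerSet(unique(rand_kmers(60, k)), model = model)
    ms <- greedySuperstring(ks)
    direct_max <- applyMaskPolicy(ms, "max-one")
    via_min <- applyMaskPolicy(applyMaskPolicy(ms, "min-one"), "max-one")
    expect_identical(maskBits(direct_max), maskBits(via_min))
    expect_identical(sum(maskBits(applyMaskPolicy(ms, "min-one"))), length(ks))
    expect_gte(sum(maskBits(direct_max)), length(ks))
    # max-one marks exactly the represented windows
    win <- windows_of(superstring(ms), k)
    if (strandModel(ks) == "bidirectional") win <- canonicalKmer(win)
    expect_identical(unname(maskBits(direct_max)[seq_along(win)]),
                     win %in% kmers(ks))
  }
})

test_that("representedSet reads marked occurrences only", {
  expect_identical(kmers(representedSet(maskedSuperstring("ACGT", "1100", 3))),
                   c("ACG", "CGT"))
  expect_identical(kmers(representedSet(maskedSuperstring("ACGT", "1000", 3))),
                   "ACG")
  expect_length(kmers(representedSet(maskedSuperstring("ACGT", "0000", 3))), 0)
})

test_that("masked superstring validity rejects malformed pairs", {
  expect_error(maskedSuperstring("ACGT", "110", k = 3), "length")
  expect_error(maskedSuperstring("ACGT", "1110", k = 3), "last k-1")
  expect_error(maskedSuperstring("ACNT", "1000", k = 3), "A,C,G,T")
})
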