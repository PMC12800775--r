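stream_index <- function(ks, mode = "memb") {
  indexKmerSet(ks, mode, withKLCP = TRUE)
}

test_that("kLCP bits equal naive adjacent-LCP thresholding", {
  expect_identical(as.integer(klcpBits(buildKLCP(buildSuffixArray("ACGT"), 3))),
                   rep(0L, 5))
  expect_identical(as.integer(klcpBits(buildKLCP(buildSuffixArray("AAAA"), 3))),
                   c(0L, 0L, 1L, 1L, 0L))
  expect_identical(as.integer(klcpBits(buildKLCP(buildSuffixArray("A"), 2))),
                   c(0L, 0L))

  set.seed(61)
  for (rep in 1:12) {
    S <- rand_dna(sample(c(5, 60, 700), 1))
    k <- sample(3:8, 1)
    sa <- buildSuffixArray(S)
    naive <- naive_adjacent_lcp(S) >= k - 1
    naive[length(naive)] <- FALSE
    expect_identical(klcpBits(buildKLCP(sa, k)), naive)
  }
})

test_that("interval extension yields the (k-1)-prefix interval, both methods", {
  ms <- maskedSuperstring("AAAA", "1100", 3, policy = "max-one")
  idx <- buildIndex(ms, "memb", withKLCP = TRUE, generalMask = TRUE)
  iv <- backwardSearch(idx, "AAA")
  expect_identical(iv, c(3L, 5L))     # suffixes AAA$, AAAA$
  expect_identical(extendToPrefixInterval(idx, iv), c(2L, 5L))  # the AA interval
  expect_identical(extendToPrefixInterval(idx, iv, "rankselect"), c(2L, 5L))

  idx2 <- stream_index(kmerSet(c("ACG", "CGT"), model = "unidirectional"))
  iv2 <- backwardSearch(idx2, "ACG")
  expect_identical(extendToPrefixInterval(idx2, iv2), iv2)  # no extension
  expect_error(extendToPrefixInterval(idx2, c(0L, 0L)), "non-empty")

  set.seed(62)
  for (rep in 1:6) {
    k <- sample(3:6, 1)
    fx <- generateFixture("random_genome", k = k, seed = rep, L = 300,
                          model = "unidirectional")
    ix <- stream_index(fx$kmers)
    S <- superstring(invertMBWT(ix@image))
    for (w in unique(windows_of(S, k))) {
      iv <- backwardSearch(ix, w)
      want <- naive_interval(S, substr(w, 1, k - 1))
      got_scan <- extendToPrefixInterval(ix, iv, "scan")
      expect_identical(got_scan, want)
      expect_identical(extendToPrefixInterval(ix, iv, "rankselect"), want)
      expect_identical(extendToPrefixInterval(ix, got_scan), got_scan)  # idempotent
    }
  }
})

test_that("streamed answers equal isolated answers on random texts", {
  set.seed(63)
  for (model in c("unidirectional", "bidirectional")) {
    fx <- generateFixture("pangenome", k = 7, seed = 64, L = 800, g = 4,
                          mu = 0.03, model = model)
    memb <- stream_index(fx$kmers)
    dict <- stream_index(fx$kmers, "dict")
    texts <- c(
      substring(fx$seq[1], 1, 250),                       # positive-rich
      vapply(1:6, function(i) rand_dna(150), ""),         # negative-rich
      paste0(substring(fx$seq[2], 10, 80), "NN",
             substring(fx$seq[1], 300, 360)),             # N breaks the chain
      rand_dna(7))                                        # degenerate |T| = k
    for (tx in texts) {
      win <- windows_of(tx, 7)
      ok <- is_dna(win)
      iso_m <- rep(FALSE, length(win))
      iso_m[ok] <- kmerMember(memb, win[ok])
      iso_l <- rep(-1L, length(win))
      iso_l[ok] <- kmerLookup(dict, win[ok])
      for (bs in list(NULL, 13L, nchar(tx))) {
        expect_identical(streamAnswers(streamQuery(memb, tx, blockSize = bs)),
                         iso_m)
        expect_identical(streamAnswers(streamQuery(dict, tx, op = "lookup",
                                                   blockSize = bs)), iso_l)
      }
    }
    expect_length(streamAnswers(streamQuery(memb, rand_dna(6))), 0)  # |T| < k
  }
})

test_that("streamed answers are invariant to the strand counter state", {
  fx <- generateFixture("pangenome", k = 7, seed = 65, L = 500, g = 3,
                        mu = 0.05, model = "bidirectional")
  idx <- stream_index(fx$kmers)
  tx <- paste0(substring(fx$seq[1], 1, 120), rand_dna(60))
  a <- streamAnswers(streamQuery(idx, tx, counter = 7L))
  b <- streamAnswers(streamQuery(idx, tx, counter = -7L))
  expect_identical(a, b)
})

test_that("positive unidirectional streams cost exactly one full search", {
  idx <- stream_index(kmerSet(c("ACG", "CGT"), model = "unidirectional"))
  r <- streamQuery(idx, "ACGT")
  expect_identical(streamAnswers(r), c(TRUE, TRUE))
  expect_identical(telemetry(r)$full_searches, 1L)

  rn <- streamQuery(idx, "AAAA")
  expect_identical(streamAnswers(rn), c(FALSE, FALSE))
  expect_identical(telemetry(rn)$full_searches, 2L)

  fx <- generateFixture("random_genome", k = 11, seed = 66, L = 4000,
                        model = "unidirectional")
  r2 <- streamQuery(stream_index(fx$kmers), fx$seq)
  expect_true(all(streamAnswers(r2)))
  expect_identical(telemetry(r2)$full_searches, 1L)
  expect_identical(telemetry(r2)$extensions, nchar(fx$seq) - 11L)
})

test_that("bidirectional block telemetry obeys the amortization accounting", {
  # strand-consistent positive stream: with the correct initial prediction,
  # each block costs exactly one seeding search. k = 15 keeps the 4-kb
  # genome free of repeated or reverse-complement-colliding 14-mers, so the
  # greedy chain is a single orientation-consistent walk.
  fx <- generateFixture("random_genome", k = 15, seed = 67, L = 4000,
                        model = "bidirectional")
  expect_false(anyDuplicated(canonicalKmer(windows_of(fx$seq, 14))) > 0)
  idx <- stream_index(fx$kmers)
  runs <- lapply(c(7L, -7L), function(cnt)
    telemetry(streamQuery(idx, fx$seq, counter = cnt)))
  expect_identical(min(vapply(runs, `[[`, 0L, "full_searches")),
                   runs[[1]]$blocks)

  # general bound: seeds <= blocks, each position missing from the strand
  # queried first costs at most one retry plus one chain re-seed
  tx <- paste0(substring(fx$seq, 1, 200), rand_dna(50),
               revComp(substring(fx$seq, 501, 700)))
  for (bs in list(NULL, 40L)) {
    tl <- telemetry(streamQuery(idx, tx, blockSize = bs, counter = 0L))
    win <- windows_of(tx, 15)
    present_fwd <- vapply(win, function(w)
      is_dna(w) && diff(backwardSearch(idx, w)) > 0, NA)
    present_rc <- vapply(win, function(w)
      is_dna(w) && diff(backwardSearch(idx, revComp(w))) > 0, NA)
    exposure <- sum(!(present_fwd & present_rc))  # positions missing somewhere
    expect_lte(tl$full_searches, tl$blocks + 2 * exposure)
    expect_lte(tl$retried, exposure)
  }
})
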