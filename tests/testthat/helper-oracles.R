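# Independent oracles (naive implementations) and small random-data helpers.
# These deliberately avoid the package's fast paths: suffix sorting via R's
# radix string sort, membership via plain hash-set lookup, LCPs via
# character-by-character comparison.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Vectorized batch of random k-mers (fast enough for 10^4+).
rand_kmers <- function(n, k) {
  m <- matrix(sample(BASES, n * k, replace = TRUE), ncol = k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE))
}

# All k-length windows of a sequence (may include non-ACGT letters).
windows_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) character(0) else substring(s, 1:(n - k + 1L), k:n)
}

# Naive suffix array of S + sentinel, 0-based. The empty suffix plays the
# sentinel: R's radix sort puts a proper prefix before its extensions, which
# is exactly the $-smallest convention.
naive_sa <- function(S) {
  n <- nchar(S)
  suf <- c(substring(S, seq_len(n)), "")
  order(suf, method = "radix") - 1L
}

naive_bwt <- function(S) {
  n <- nchar(S) + 1L
  sa <- naive_sa(S)
  chars <- c(strsplit(S, "", fixed = TRUE)[[1]], "$")
  paste(chars[(sa - 1L) %% n + 1L], collapse = "")
}

# Adjacent LCPs of the sorted suffixes of S + sentinel (last entry 0).
naive_adjacent_lcp <- function(S) {
  n <- nchar(S)
  chars <- strsplit(S, "", fixed = TRUE)[[1]]
  sa <- naive_sa(S)
  out <- integer(n + 1L)
  for (t in seq_len(n)) {          # pairs (t-1, t) in 0-based rank space
    p <- sa[t] ; q <- sa[t + 1L]   # 0-based text positions
    h <- 0L
    while (p + h < n && q + h < n && chars[p + h + 1L] == chars[q + h + 1L])
      h <- h + 1L
    out[t] <- h
  }
  out
}

# Naive SA interval of a pattern: ranks of suffixes having it as a prefix.
naive_interval <- function(S, pat) {
  n <- nchar(S)
  sa <- naive_sa(S)
  suf <- c(substring(S, seq_len(n)), "")[sa + 1L]
  hit <- startsWith(suf, pat)
  if (!any(hit)) return(c(0L, 0L))
  c(min(which(hit)) - 1L, max(which(hit)))
}

# Hash-set membership oracle under a strand model.
oracle_member <- function(Q, ks) {
  if (strandModel(ks) == "bidirectional") Q <- canonicalKmer(Q)
  Q %in% kmers(ks)
}

# Random masked superstring with a structurally valid mask (last k-1 bits 0).
rand_ms <- function(len, k = 3L, model = "unidirectional") {
  S <- if (len > 0) rand_dna(len) else ""
  M <- if (len > 0) runif(len) < 0.5 else logical(0)
  if (len > 0) {
    tl <- min(k - 1L, len)
    M[seq(len - tl + 1L, len)] <- FALSE
  }
  maskedSuperstring(S, M, k = k, model = model)
}
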