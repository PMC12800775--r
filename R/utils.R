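# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
MBWT_ALPHABET <- c("$", "A", "C", "G", "T")

is_dna <- function(x) {
  !is.na(x) & grepl("^[ACGT]*$", x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- which(!is_dna(x))
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-ACGT characters (first offender: element %d)",
                 what, bad[1]), call. = FALSE)
  }
  invisible(x)
}

assert_model <- function(model) {
  match.arg(model, c("unidirectional", "bidirectional"))
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Bit masks travel as logical vectors internally but "1100"-style strings are
# convenient at the surface; accept both.
as_mask_bits <- function(M) {
  if (is.character(M)) {
    stopifnot(length(M) == 1L)
    if (nchar(M) == 0L) return(logical(0))
    bits <- strsplit(M, "", fixed = TRUE)[[1]]
    if (!all(bits %in% c("0", "1"))) stop("mask string must be over {0,1}", call. = FALSE)
    return(bits == "1")
  }
  if (is.numeric(M)) M <- M != 0
  if (!is.logical(M) || anyNA(M)) stop("mask must be a logical/0-1 vector or bit string", call. = FALSE)
  as.logical(M)
}

mask_to_string <- function(bits) paste(as.integer(bits), collapse = "")
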