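# File formats: plain FASTA ingestion (via Biostrings), the case-encoded
# masked-superstring FASTA interchange format (uppercase = mask 1), and the
# JSON index archive (stores the masked superstring + metadata; derived
# structures are rebuilt deterministically on load).

ARCHIVE_MAGIC <- "MBWT-INDEX"
ARCHIVE_VERSION <- 1L

#' Read DNA sequences from a FASTA file
#'
#' Multi-record FASTA, gzip-transparent, CRLF tolerated; sequence case is
#' normalized upward (case is reserved for mask encoding in the
#' masked-superstring format only, see [readMaskedSuperstring()]).
#'
#' @param path readable FASTA file, optionally gzipped.
#' @return named character vector of upper-case sequences, in file order.
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 25L, warn = FALSE)
  nonempty <- which(nzchar(trimws(first)))
  if (length(nonempty) > 0 && !startsWith(trimws(first[nonempty[1]]), ">"))
    stop(sprintf("malformed FASTA in '%s': line %d does not start a record",
                 path, nonempty[1]))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("malformed FASTA in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

encode_case_mask <- function(S, M) {
  if (nchar(S) == 0) return("")
  chars <- strsplit(S, "", fixed = TRUE)[[1]]
  chars[!M] <- tolower(chars[!M])
  paste(chars, collapse = "")
}

decode_case_mask <- function(txt) {
  if (nchar(txt) == 0) return(list(S = "", M = logical(0)))
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "a", "c", "g", "t")))
    stop("masked-superstring letters must be in {ACGTacgt}")
  list(S = toupper(txt), M = chars %in% c("A", "C", "G", "T"))
}

#' Write / read the case-encoded masked-superstring FASTA format
#'
#' The interchange format for masked superstrings: one FASTA record whose
#' header carries `k=<int> model=<uni|bi>` (and, informatively,
#' `policy=<...>`), and whose sequence is the superstring with uppercase
#' letters at mask-1 positions and lowercase letters at mask-0 positions.
#' `readMaskedSuperstring()` is the exact inverse of
#' `writeMaskedSuperstring()`.
#'
#' @param ms a [MaskedSuperstring-class].
#' @param path output / input file path.
#' @param name record name written after `>`.
#' @return `writeMaskedSuperstring()` returns `path` invisibly;
#'   `readMaskedSuperstring()` returns a [MaskedSuperstring-class].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeMaskedSuperstring(maskedSuperstring("ACGT", "1100", k = 3), f)
#' readLines(f)[2]  # "ACgt"
#' @export
writeMaskedSuperstring <- function(ms, path, name = "superstring") {
  stopifnot(is(ms, "MaskedSuperstring"))
  model_tag <- if (ms@model == "bidirectional") "bi" else "uni"
  header <- sprintf(">%s k=%d model=%s policy=%s", name, ms@k, model_tag,
                    ms@policy)
  body <- encode_case_mask(ms@S, ms@M)
  lines <- if (nchar(body) > 0) {
    substring(body, seq(1L, nchar(body), 70L),
              pmin(seq(1L, nchar(body), 70L) + 69L, nchar(body)))
  } else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname writeMaskedSuperstring
#' @export
readMaskedSuperstring <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty masked-superstring file: ", path)
  first <- which(keep)[1]
  header <- trimws(lines[first])
  if (!startsWith(header, ">"))
    stop(sprintf("format error at line %d: expected a '>' header", first))
  km <- regmatches(header, regexpr("\\bk=[0-9]+", header))
  if (length(km) == 0)
    stop(sprintf("format error at line %d: header is missing k=<int>", first))
  k <- as.integer(sub("k=", "", km))
  mm <- regmatches(header, regexpr("\\bmodel=(uni|bi)\\b", header))
  if (length(mm) == 0)
    stop(sprintf("format error at line %d: header is missing model=<uni|bi>", first))
  model <- if (identical(mm, "model=bi")) "bidirectional" else "unidirectional"
  pm <- regmatches(header, regexpr("\\bpolicy=[a-z-]+", header))
  policy <- if (length(pm) == 1) sub("policy=", "", pm) else "unoptimized"
  if (!policy %in% c("min-one", "max-one", "unoptimized")) policy <- "unoptimized"
  rest <- lines[-seq_len(first)]
  if (any(startsWith(trimws(rest), ">")))
    stop("masked-superstring file must contain exactly one record")
  body <- paste(trimws(rest), collapse = "")
  dec <- decode_case_mask(body)
  new("MaskedSuperstring", S = dec$S, M = dec$M, k = k, model = model,
      policy = policy)
}

#' Save / load an index archive
#'
#' The archive stores the case-encoded masked superstring plus metadata
#' (magic tag, format version, k, model, mode, mask policy, kLCP flag) as
#' JSON; the derived structures (suffix array, BWT, rank/select, kLCP) are
#' rebuilt deterministically on load, so a loaded index answers identically
#' to the saved one on every query. Magic or version mismatches and
#' truncated files raise an archive error.
#'
#' @param index an [MBWTIndex-class].
#' @param path archive file path.
#' @return `saveIndex()` returns `path` invisibly; `loadIndex()` returns an
#'   [MBWTIndex-class].
#' @export
saveIndex <- function(index, path) {
  stopifnot(is(index, "MBWTIndex"))
  ms <- invertMBWT(index@image)
  payload <- list(
    magic = ARCHIVE_MAGIC, version = ARCHIVE_VERSION,
    k = index@image@k, model = index@image@model, mode = index@mode,
    policy = index@image@policy, general = index@general,
    klcp = length(index@klcp) > 0,
    superstring = encode_case_mask(ms@S, ms@M))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e)
                        stop("archive error: unreadable index archive (",
                             conditionMessage(e), ")", call. = FALSE))
  if (!identical(payload$magic, ARCHIVE_MAGIC))
    stop("archive error: bad magic tag (not an index archive?)")
  if (!identical(as.integer(payload$version), ARCHIVE_VERSION))
    stop(sprintf("archive error: unsupported format version %s (expected %d)",
                 payload$version, ARCHIVE_VERSION))
  dec <- decode_case_mask(payload$superstring)
  ms <- new("MaskedSuperstring", S = dec$S, M = dec$M,
            k = as.integer(payload$k), model = payload$model,
            policy = payload$policy)
  buildIndex(ms, payload$mode, withKLCP = isTRUE(payload$klcp),
             generalMask = isTRUE(payload$general))
}
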