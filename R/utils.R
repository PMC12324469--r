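# Internal utilities: CURIE handling, deterministic hashing, JSON Lines I/O,
# and structured logging with reason codes.

#' Is a string a well-formed CURIE?
#'
#' A CURIE is `prefix:local-id` with non-empty prefix and local id and exactly
#' one colon. Bare DrugBank accessions (`DB` followed by digits) are accepted
#' as a namespace-bearing identifier even though they carry no colon, because
#' mechanism corpora serialize DrugBank drugs that way.
#'
#' @param x character vector of candidate identifiers.
#' @return logical vector.
#' @export
is_curie <- function(x) {
  if (length(x) == 0L) return(logical(0))
  ok <- !is.na(x) & nzchar(x)
  colon <- grepl("^[^:]+:[^:]+$", x)
  drugbank <- grepl("^DB[0-9]+$", x)
  ok & (colon | drugbank)
}

#' Namespace prefix of a CURIE (lower-cased)
#'
#' Prefix comparison is case-insensitive throughout the package
#' (`"chebi:"` is equivalent to `"CHEBI:"`); local ids are compared verbatim.
#' Bare DrugBank accessions report prefix `"db"`.
#'
#' @param x character vector of CURIEs.
#' @return lower-cased prefixes; `NA` where `x` is not a CURIE.
#' @export
curie_prefix <- function(x) {
  out <- rep(NA_character_, length(x))
  bare <- grepl("^DB[0-9]+$", x)
  out[bare] <- "db"
  has_colon <- grepl(":", x, fixed = TRUE) & !bare
  out[has_colon] <- tolower(sub(":.*$", "", x[has_colon]))
  out
}

#' Short stable content hash
#'
#' 12 hex characters of SHA-1; used for reproducible item ids and cache keys.
#' @param x an R object (serialized canonically via its character form).
#' @return a 12-character hex string.
#' @export
stable_hash <- function(x) {
  substr(digest::digest(x, algo = "sha1"), 1L, 12L)
}

# Evaluate `code` under a fixed RNG seed without disturbing global RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Write records as JSON Lines
#'
#' One JSON object per line, UTF-8, scalar fields unboxed.
#'
#' @param records list of named lists.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read JSON Lines into a list of records
#'
#' @param path file path.
#' @return list of named lists, one per non-empty line.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

# One-line structured log with a reason code; suppressed unless
# options(bterag.verbose = TRUE). Warnings still go through warning().
log_event <- function(stage, code, detail = "") {
  if (isTRUE(getOption("bterag.verbose", FALSE))) {
    message(sprintf("[bterag] %s %s %s", stage, code, detail))
  }
  invisible(NULL)
}

# Normalized whitespace: trimmed, internal runs collapsed to one space.
squish <- function(x) gsub("\\s+", " ", trimws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
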