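# Context selection: score verbalized statements against the question by
# embedding cosine similarity and prune the lowest-scoring percentile.

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| * |v|)`, in `[-1, 1]`. Errors on zero vectors (the
#' similarity is undefined there) and on dimension mismatch.
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar similarity.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("cosine: dimension mismatch", call. = FALSE)
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("cosine: undefined similarity for zero vector", call. = FALSE)
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

#' Construct an embedder object
#'
#' An embedder is a deterministic map from text to a fixed-length numeric
#' vector. The package ships the token-hash embedder for offline use
#' ([make_hash_embedder()]); production configurations name a sentence-
#' transformer model id instead, plugged in through the same contract.
#'
#' @param embed function(text) -> numeric vector.
#' @param dimension vector length produced by `embed`.
#' @param id configuration string identifying the embedding model.
#' @return an `embedder` object.
#' @export
new_embedder <- function(embed, dimension, id) {
  stopifnot(is.function(embed), dimension >= 1L)
  structure(list(embed = embed, dimension = as.integer(dimension), id = id),
            class = "embedder")
}

#' @export
print.embedder <- function(x, ...) {
  cat(sprintf("<embedder '%s', dimension %d>\n", x$id, x$dimension))
  invisible(x)
}

strip_provenance <- function(text) sub(" \\(source: [^)]*\\)$", "", text)

#' Score context statements against a question
#'
#' Each statement receives `cosine(embed(question), embed(text))`. By default
#' the provenance suffix is excluded from the scored text so source tokens do
#' not distort similarity. Statements with empty text score the sentinel
#' minimum (-1). Input order is preserved.
#'
#' @param question question text.
#' @param statements list of `context_statement`s.
#' @param embedder an `embedder`.
#' @param score_provenance include the `" (source: ...)"` suffix in scoring?
#' @return list of `scored_statement`s (`statement` + `score`).
#' @export
score_statements <- function(question, statements, embedder,
                             score_provenance = FALSE) {
  if (!length(statements)) return(list())
  qv <- embedder$embed(question)
  lapply(statements, function(s) {
    txt <- if (score_provenance) s$text else strip_provenance(s$text)
    score <- if (!nzchar(squish(txt))) {
      log_event("context_select", "empty_statement_text", s$subject_curie)
      -1
    } else {
      cosine(qv, embedder$embed(txt))
    }
    structure(list(statement = s, score = score), class = "scored_statement")
  })
}

#' Filter scored statements by percentile
#'
#' Drops the `k = floor(p * n / 100)` lowest-scored statements. Ties are
#' broken by original position: among equal scores, earlier statements
#' survive. The relative order of survivors is preserved. This count-based
#' rule realizes both the "lowest p% removed" and the "retain above the p-th
#' percentile" phrasings unambiguously, including at small n and with ties.
#'
#' @param scored list of `scored_statement`s.
#' @param p percentile in `[0, 100]`.
#' @return the kept `scored_statement`s.
#' @export
filter_by_percentile <- function(scored, p) {
  stopifnot(p >= 0, p <= 100)
  n <- length(scored)
  if (n == 0L) return(list())
  k <- floor(p * n / 100)
  if (k == 0L) return(scored)
  scores <- vapply(scored, function(s) s$score, numeric(1))
  # ascending score; ties yield to later positions first
  ord <- order(scores, -seq_len(n))
  drop_idx <- ord[seq_len(k)]
  scored[sort(setdiff(seq_len(n), drop_idx))]
}

#' Export scored statements as TSV (rank, score, text)
#'
#' Ranked by descending score; rank 1 is the most question-similar statement.
#'
#' @param scored list of `scored_statement`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scored_tsv <- function(scored, path) {
  scores <- vapply(scored, function(s) s$score, numeric(1))
  texts <- vapply(scored, function(s) s$statement$text, character(1))
  ord <- order(scores, decreasing = TRUE)
  df <- data.frame(rank = seq_along(ord), score = scores[ord], text = texts[ord],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
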