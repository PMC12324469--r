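# Answer evaluation: exact-match and semantic-concordance scoring plus the
# derived analytics (accuracy summaries, flip cross-tabulations, rank-ordered
# similarity curves, histograms, high-fidelity counts).

#' Exact (case-insensitive) string match
#'
#' True iff the lower-cased, whitespace-trimmed strings are equal.
#'
#' @param prediction,truth character scalars.
#' @return logical flag.
#' @export
exact_match <- function(prediction, truth) {
  identical(tolower(trimws(prediction)), tolower(trimws(truth)))
}

#' Semantic similarity of prediction and reference
#'
#' Cosine similarity of the two texts' embeddings. An empty (or parse-failed)
#' prediction scores the sentinel -1 rather than being excluded, so failures
#' depress rather than inflate accuracy.
#'
#' @param prediction model answer (may be empty).
#' @param truth non-empty reference answer.
#' @param embedder an `embedder`.
#' @return similarity in `[-1, 1]`.
#' @export
semantic_similarity <- function(prediction, truth, embedder) {
  stopifnot(nzchar(truth))
  if (is.na(prediction) || !nzchar(trimws(prediction))) return(-1)
  cosine(embedder$embed(prediction), embedder$embed(truth))
}

#' Classify a similarity score as accurate
#'
#' Inclusive threshold: `score >= threshold`. The inclusive boundary matches
#' the high-fidelity convention (cosine >= 0.90) and is used everywhere for
#' consistency.
#'
#' @param score similarity score.
#' @param threshold value in `[0, 1]`.
#' @return logical flag.
#' @export
classify_accurate <- function(score, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  score >= threshold
}

#' Summarize answer records against ground truth
#'
#' Joins records to truths on `item_id`, computes per-item correctness
#' (`exact` scoring: case-insensitive match; `semantic` scoring: embedding
#' similarity at `threshold`), and reports accuracy over all records --- parse
#' failures count as incorrect. `n_at_or_above` counts records whose semantic
#' similarity reaches each requested threshold (defaults 0.80 and 0.90, the
#' high-fidelity zones).
#'
#' @param records list of `answer_record`s (see [run_item()]).
#' @param truths list of `qa_item`s, joinable on `item_id`.
#' @param scoring `"exact"` or `"semantic"`.
#' @param thresholds similarity thresholds for the `n_at_or_above` counts.
#' @param embedder an `embedder`; required for `n_at_or_above` and for
#'   semantic scoring.
#' @param threshold similarity at or above which a semantic answer counts as
#'   correct (default 0.90).
#' @return an `eval_summary`: `n`, `n_correct`, `accuracy` (NA when n = 0),
#'   `n_at_or_above` (named integer vector), `correct` (per-item flags, named
#'   by item_id), `scores` (per-item similarities, or NULL without embedder).
#' @export
summarize_eval <- function(records, truths, scoring = c("exact", "semantic"),
                           thresholds = c(0.80, 0.90), embedder = NULL,
                           threshold = 0.90) {
  scoring <- match.arg(scoring)
  truth_by_id <- stats::setNames(
    lapply(truths, identity),
    vapply(truths, function(t) t$item_id, character(1))
  )
  n <- length(records)
  correct <- logical(n)
  scores <- if (!is.null(embedder)) numeric(n) else NULL
  ids <- character(n)
  for (i in seq_along(records)) {
    r <- records[[i]]
    tr <- truth_by_id[[r$item_id]]
    if (is.null(tr)) stop(sprintf("no ground truth for item_id '%s'", r$item_id),
                          call. = FALSE)
    ids[i] <- r$item_id
    sim <- if (!is.null(embedder)) {
      semantic_similarity(r$answer, tr$truth_label, embedder)
    } else NA_real_
    if (!is.null(scores)) scores[i] <- sim
    correct[i] <- switch(scoring,
      exact = isTRUE(r$parse_ok) && exact_match(r$answer, tr$truth_label),
      semantic = {
        if (is.null(embedder)) stop("semantic scoring requires an embedder", call. = FALSE)
        classify_accurate(sim, threshold)
      }
    )
  }
  n_at <- if (!is.null(scores)) {
    stats::setNames(
      vapply(thresholds, function(th) sum(scores >= th), integer(1)),
      format(thresholds)
    )
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(
    list(
      n = n,
      n_correct = sum(correct),
      accuracy = if (n > 0) sum(correct) / n else NA_real_,
      n_at_or_above = n_at,
      correct = stats::setNames(correct, ids),
      scores = if (!is.null(scores)) stats::setNames(scores, ids) else NULL
    ),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary n=%d correct=%d accuracy=%s>\n",
              x$n, x$n_correct,
              ifelse(is.na(x$accuracy), "NA", sprintf("%.3f", x$accuracy))))
  if (length(x$n_at_or_above)) {
    cat("  n at or above:",
        paste(sprintf("%s: %d", names(x$n_at_or_above), x$n_at_or_above),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank-ordered similarity curve
#'
#' Scores sorted ascending (stable sort), the form in which per-question
#' similarity traces are plotted lowest-to-highest.
#'
#' @param scores numeric vector of similarities.
#' @return `similarity_curve` (numeric vector, non-decreasing).
#' @export
rank_curve <- function(scores) {
  structure(sort(scores, method = "radix"), class = "similarity_curve")
}

#' Histogram of similarity scores
#'
#' Bins `[k*w, (k+1)*w)` tile `[0, 1]`; the final bin is right-closed so a
#' score of exactly 1.0 is counted. Negative scores (the empty-answer
#' sentinel) pool into an `underflow` bin. Counts always sum to `n`.
#'
#' @param scores numeric similarities.
#' @param bin_width bin width in `(0, 1]` (default 0.05).
#' @return named integer vector of counts, names like `"[0.90,0.95)"`.
#' @export
bin_histogram <- function(scores, bin_width = 0.05) {
  stopifnot(bin_width > 0, bin_width <= 1)
  nb <- ceiling(1 / bin_width - 1e-9)
  lows <- (seq_len(nb) - 1L) * bin_width
  highs <- pmin(lows + bin_width, 1)
  labels <- sprintf("[%.2f,%.2f%s", lows, highs,
                    ifelse(seq_len(nb) == nb, "]", ")"))
  counts <- integer(nb)
  under <- 0L
  for (s in scores) {
    if (is.na(s)) next
    if (s < 0) {
      under <- under + 1L
    } else {
      k <- min(floor(s / bin_width + 1e-9), nb - 1L)
      counts[k + 1L] <- counts[k + 1L] + 1L
    }
  }
  stats::setNames(c(under, counts), c("underflow", labels))
}

#' Cross-tabulate correctness flips between two inference modes
#'
#' 2x2 table of per-item correctness under the baseline (LLM-only) versus the
#' augmented (retrieval) run. Inputs must be aligned by item: equal lengths,
#' same order.
#'
#' @param baseline_flags,augmented_flags logical vectors.
#' @return a `flip_table`: `both_correct`, `flipped_to_correct`,
#'   `flipped_to_incorrect`, `both_incorrect`.
#' @export
crosstab_flips <- function(baseline_flags, augmented_flags) {
  if (length(baseline_flags) != length(augmented_flags)) {
    stop("flip cross-tabulation requires aligned flag vectors", call. = FALSE)
  }
  structure(
    list(
      both_correct = sum(baseline_flags & augmented_flags),
      flipped_to_correct = sum(!baseline_flags & augmented_flags),
      flipped_to_incorrect = sum(baseline_flags & !augmented_flags),
      both_incorrect = sum(!baseline_flags & !augmented_flags)
    ),
    class = "flip_table"
  )
}

#' @export
print.flip_table <- function(x, ...) {
  cat("<flip_table>\n")
  cat(sprintf("  both correct:         %d\n", x$both_correct))
  cat(sprintf("  flipped to correct:   %d\n", x$flipped_to_correct))
  cat(sprintf("  flipped to incorrect: %d\n", x$flipped_to_incorrect))
  cat(sprintf("  both incorrect:       %d\n", x$both_incorrect))
  invisible(x)
}
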