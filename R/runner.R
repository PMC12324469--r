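# Orchestration of the dual-path experiment: for each benchmark item,
# retrieve knowledge-graph context (augmented mode only), prune it at the
# configured similarity percentile, run both inference modes on identical
# questions through one deterministic backend, score, and emit analytics.

#' Experiment configuration
#'
#' @param benchmark benchmark file path (JSON Lines) or a list of `qa_item`s.
#' @param modes subset of `c("llm_only", "bte_rag")`; at least one.
#' @param percentile context-pruning percentile in `[0, 100]` (0 = keep all).
#' @param backend generation backend (`list(id, generate)`).
#' @param transport TRAPI transport callable (required when `"bte_rag"` is
#'   among the modes).
#' @param selection_embedder embedder used to score context against the
#'   question.
#' @param eval_embedder embedder used for semantic answer scoring.
#' @param scoring `"exact"` (gene benchmark) or `"semantic"`.
#' @param thresholds high-fidelity thresholds reported by the summaries.
#' @param semantic_threshold similarity at or above which a semantic answer
#'   counts correct.
#' @param answer_key structured-output key; defaults per benchmark.
#' @param templates prompt templates.
#' @param out_dir optional output directory for report files.
#' @param cache_dir optional retrieval cache directory.
#' @param seed recorded in the manifest (the pipeline itself is deterministic
#'   given its backend/transport fixtures).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(benchmark, modes = c("llm_only", "bte_rag"),
                              percentile = 0, backend = NULL, transport = NULL,
                              selection_embedder = make_hash_embedder(),
                              eval_embedder = make_hash_embedder(),
                              scoring = c("exact", "semantic"),
                              thresholds = c(0.80, 0.90),
                              semantic_threshold = 0.90,
                              answer_key = NULL,
                              templates = default_prompt_templates(),
                              out_dir = NULL, cache_dir = NULL, seed = 1L) {
  scoring <- match.arg(scoring)
  stopifnot(length(modes) >= 1L, all(modes %in% c("llm_only", "bte_rag")),
            percentile >= 0, percentile <= 100)
  structure(
    list(benchmark = benchmark, modes = modes, percentile = percentile,
         backend = backend, transport = transport,
         selection_embedder = selection_embedder,
         eval_embedder = eval_embedder, scoring = scoring,
         thresholds = thresholds, semantic_threshold = semantic_threshold,
         answer_key = answer_key, templates = templates,
         out_dir = out_dir, cache_dir = cache_dir, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run the dual-path experiment
#'
#' Items are processed in benchmark order. For `bte_rag`, each item's context
#' is retrieved through the configured transport, scored against the question
#' with the selection embedder, and pruned at the configured percentile; both
#' modes then answer identical questions through the same backend. Outputs are
#' per-mode answer records, per-mode evaluation summaries, and (when both
#' modes run) the flip cross-tabulation. With `out_dir` set, report files are
#' written: `records_{mode}.jsonl`, `summary.tsv`, `flips.tsv`,
#' `curve_{mode}.tsv`, `hist_{mode}.tsv` and `manifest.json`.
#'
#' @param config an [experiment_config()].
#' @return list with `items`, `records` (per mode), `summaries` (per mode),
#'   `flips` (or NULL), `files` (written paths).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  items <- if (is.character(config$benchmark)) read_benchmark(config$benchmark)
           else config$benchmark
  if (!length(items)) stop("benchmark is empty", call. = FALSE)
  if (is.null(config$backend)) stop("no generation backend configured", call. = FALSE)
  if ("bte_rag" %in% config$modes && is.null(config$transport)) {
    stop("bte_rag mode requires a transport", call. = FALSE)
  }
  benchmark_kind <- items[[1]]$benchmark
  answer_key <- config$answer_key %||% default_answer_keys()[[benchmark_kind]]
  gen_config <- make_generation_config(answer_key, temperature = 0,
                                       backend_id = config$backend$id %||% "backend")

  records <- stats::setNames(
    replicate(length(config$modes), vector("list", length(items)), simplify = FALSE),
    config$modes
  )
  for (i in seq_along(items)) {
    item <- items[[i]]
    kept <- NULL
    if ("bte_rag" %in% config$modes) {
      statements <- retrieve_for_item(item, config$transport, config$cache_dir)
      scored <- score_statements(item$question, statements, config$selection_embedder)
      kept <- filter_by_percentile(scored, config$percentile)
      log_event("runner", "context",
                sprintf("%s retrieved=%d kept=%d", item$item_id,
                        length(statements), length(kept)))
    }
    for (mode in config$modes) {
      records[[mode]][[i]] <- run_item(
        item, config$backend,
        statements = if (mode == "bte_rag") kept else NULL,
        config = gen_config, templates = config$templates
      )
    }
  }

  summaries <- lapply(records, function(rs) {
    summarize_eval(rs, items, scoring = config$scoring,
                   thresholds = config$thresholds,
                   embedder = config$eval_embedder,
                   threshold = config$semantic_threshold)
  })
  flips <- if (all(c("llm_only", "bte_rag") %in% config$modes)) {
    crosstab_flips(unname(summaries$llm_only$correct),
                   unname(summaries$bte_rag$correct))
  } else NULL

  files <- character(0)
  if (!is.null(config$out_dir)) {
    files <- write_experiment_reports(config, items, records, summaries, flips)
  }
  list(items = items, records = records, summaries = summaries, flips = flips,
       files = files)
}

write_experiment_reports <- function(config, items, records, summaries, flips) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (mode in names(records)) {
    f <- file.path(dir, sprintf("records_%s.jsonl", mode))
    write_answer_records(records[[mode]], f)
    files <- c(files, f)
    s <- summaries[[mode]]
    if (!is.null(s$scores)) {
      cf <- file.path(dir, sprintf("curve_%s.tsv", mode))
      utils::write.table(
        data.frame(rank = seq_len(s$n), score = as.numeric(rank_curve(unname(s$scores)))),
        cf, sep = "\t", quote = FALSE, row.names = FALSE)
      hf <- file.path(dir, sprintf("hist_%s.tsv", mode))
      h <- bin_histogram(unname(s$scores))
      utils::write.table(data.frame(bin = names(h), count = as.integer(h)),
                         hf, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, cf, hf)
    }
  }
  sf <- file.path(dir, "summary.tsv")
  sm <- do.call(rbind, lapply(names(summaries), function(mode) {
    s <- summaries[[mode]]
    row <- data.frame(mode = mode, n = s$n, accuracy = s$accuracy,
                      stringsAsFactors = FALSE)
    for (th in names(s$n_at_or_above)) {
      row[[paste0("n_ge_", th)]] <- s$n_at_or_above[[th]]
    }
    row
  }))
  utils::write.table(sm, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, sf)
  if (!is.null(flips)) {
    ff <- file.path(dir, "flips.tsv")
    utils::write.table(
      data.frame(cell = c("both_correct", "flipped_to_correct",
                          "flipped_to_incorrect", "both_incorrect"),
                 count = c(flips$both_correct, flips$flipped_to_correct,
                           flips$flipped_to_incorrect, flips$both_incorrect)),
      ff, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, ff)
  }
  mf <- file.path(dir, "manifest.json")
  manifest <- list(
    n_items = length(items),
    benchmark = items[[1]]$benchmark,
    modes = as.list(names(records)),
    percentile = config$percentile,
    scoring = config$scoring,
    backend_id = config$backend$id %||% "backend",
    selection_embedder = config$selection_embedder$id,
    eval_embedder = config$eval_embedder$id,
    template_version = config$templates$version,
    seed = config$seed
  )
  manifest$config_hash <- stable_hash(manifest)
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  c(files, mf)
}

#' Percentile pruning sweep
#'
#' Re-runs the augmented arm of an experiment at each percentile in
#' `percentiles`, reusing one retrieval pass per item, and reports the
#' per-percentile evaluation summaries. This reproduces the
#' progressively-discarding-context analysis.
#'
#' @param config an [experiment_config()] (its `percentile` is ignored).
#' @param percentiles percentiles to sweep (default 0, 10, ..., 90).
#' @return named list of `eval_summary`, one per percentile.
#' @export
percentile_sweep <- function(config, percentiles = seq(0, 90, by = 10)) {
  stopifnot(inherits(config, "experiment_config"))
  items <- if (is.character(config$benchmark)) read_benchmark(config$benchmark)
           else config$benchmark
  benchmark_kind <- items[[1]]$benchmark
  answer_key <- config$answer_key %||% default_answer_keys()[[benchmark_kind]]
  gen_config <- make_generation_config(answer_key, temperature = 0)
  scored_by_item <- lapply(items, function(item) {
    statements <- retrieve_for_item(item, config$transport, config$cache_dir)
    score_statements(item$question, statements, config$selection_embedder)
  })
  out <- lapply(percentiles, function(p) {
    recs <- lapply(seq_along(items), function(i) {
      kept <- filter_by_percentile(scored_by_item[[i]], p)
      run_item(items[[i]], config$backend, statements = kept,
               config = gen_config, templates = config$templates)
    })
    summarize_eval(recs, items, scoring = config$scoring,
                   thresholds = config$thresholds,
                   embedder = config$eval_embedder,
                   threshold = config$semantic_threshold)
  })
  stats::setNames(out, paste0("p", percentiles))
}
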