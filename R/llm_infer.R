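# Prompt assembly, pluggable generation backends, and strict structured-
# answer parsing for the two inference routes: LLM-only (question alone) and
# retrieval-augmented (context statements prepended to the question).
#
# Decoding is deterministic by convention (temperature 0), so a full item ->
# answer-record run is a pure function of (item, statements, config) for any
# deterministic backend.

TEMPLATE_VERSION <- "1.0"

#' Per-benchmark structured-output answer keys
#'
#' The key under which a backend must return its answer in the structured
#' JSON reply.
#' @return named character vector: gene, metabolite, drug.
#' @export
default_answer_keys <- function() {
  c(gene = "gene", metabolite = "biochemical_entity", drug = "drug")
}

#' Load the shipped prompt templates
#'
#' System prompts are editable plain-text files under
#' `system.file("templates", package = "bterag")`, one per benchmark per mode
#' plus the entity-extraction prompt, each mandating a single JSON object with
#' the benchmark's answer key (`{answer_key}` placeholder). User templates
#' carry `{context}` / `{question}` placeholders. The set is versioned so a
#' run manifest records which wording was used.
#'
#' @param dir directory of template files (defaults to the installed set).
#' @return `prompt_templates` list: `system[[benchmark]][[mode]]`, `user`,
#'   `extract`, `version`.
#' @export
default_prompt_templates <- function(dir = system.file("templates", package = "bterag")) {
  read_tpl <- function(name) {
    paste(readLines(file.path(dir, name), encoding = "UTF-8", warn = FALSE),
          collapse = "\n")
  }
  benchmarks <- c("gene", "metabolite", "drug")
  system <- lapply(stats::setNames(benchmarks, benchmarks), function(b) {
    list(
      llm_only = read_tpl(sprintf("system_%s_llm_only.txt", b)),
      bte_rag = read_tpl(sprintf("system_%s_bte_rag.txt", b))
    )
  })
  structure(
    list(
      system = system,
      user = list(
        llm_only = "{question}",
        bte_rag = "Context:\n{context}\n\nQuestion: {question}"
      ),
      extract = read_tpl("system_extract.txt"),
      version = TEMPLATE_VERSION
    ),
    class = "prompt_templates"
  )
}

fill_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), values[[key]], template, fixed = TRUE)
  }
  template
}

#' Generation configuration
#'
#' @param answer_key key expected in the structured reply.
#' @param temperature sampling temperature; 0 (the default) forces
#'   deterministic decoding, required for reproducible runs.
#' @param max_output_tokens completion budget hint for live adapters.
#' @param backend_id configuration string naming the backend.
#' @return a `generation_config`.
#' @export
make_generation_config <- function(answer_key, temperature = 0,
                                   max_output_tokens = 512L,
                                   backend_id = "scripted") {
  stopifnot(nzchar(answer_key), temperature >= 0)
  structure(
    list(answer_key = answer_key, temperature = temperature,
         max_output_tokens = as.integer(max_output_tokens),
         backend_id = backend_id),
    class = "generation_config"
  )
}

#' Assemble the prompt for one item and mode
#'
#' `llm_only` bundles carry the question alone as user text; `bte_rag`
#' bundles prepend one context statement per line (in the given order) before
#' the question. No few-shot examples are ever included; the system text
#' instructs structured JSON output under the benchmark's answer key.
#'
#' @param item a `qa_item`.
#' @param statements list of `context_statement`s / `scored_statement`s, or
#'   `NULL` for `llm_only`. An empty list is legal in `bte_rag` mode and is
#'   marked "(no context retrieved)".
#' @param mode `"llm_only"` or `"bte_rag"`.
#' @param templates a `prompt_templates` set.
#' @param answer_key answer key; defaults to the benchmark's key.
#' @return a `prompt_bundle`: `system_text`, `user_text`, `mode`.
#' @export
assemble_prompt <- function(item, statements = NULL,
                            mode = c("llm_only", "bte_rag"),
                            templates = default_prompt_templates(),
                            answer_key = default_answer_keys()[[item$benchmark]]) {
  mode <- match.arg(mode)
  system_text <- fill_template(templates$system[[item$benchmark]][[mode]],
                               list(answer_key = answer_key))
  if (mode == "llm_only") {
    user_text <- fill_template(templates$user$llm_only,
                               list(question = item$question))
  } else {
    if (is.null(statements)) {
      stop("bte_rag mode requires a statement list (possibly empty)", call. = FALSE)
    }
    texts <- vapply(statements, function(s) {
      if (inherits(s, "scored_statement")) s$statement$text else s$text
    }, character(1))
    context <- if (length(texts)) paste(texts, collapse = "\n") else "(no context retrieved)"
    user_text <- fill_template(templates$user$bte_rag,
                               list(context = context, question = item$question))
  }
  structure(list(system_text = system_text, user_text = user_text, mode = mode),
            class = "prompt_bundle")
}

# Strip optional markdown code fences and isolate the first balanced JSON
# object in a backend reply.
extract_first_json_object <- function(text) {
  if (grepl("```", text, fixed = TRUE)) {
    m <- regmatches(text, regexpr("```[a-zA-Z]*\\s*([\\s\\S]*?)```", text, perl = TRUE))
    if (length(m)) {
      text <- sub("^```[a-zA-Z]*\\s*", "", m[[1]])
      text <- sub("```$", "", text)
    }
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  start <- NA_integer_
  depth <- 0L
  in_str <- FALSE
  esc <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == "\"") in_str <- FALSE
      next
    }
    if (ch == "\"") { in_str <- TRUE; next }
    if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) {
          return(paste(chars[start:i], collapse = ""))
        }
      }
    }
  }
  NULL
}

#' Parse a strict structured answer
#'
#' Strips optional code fences, parses the first JSON object in the reply,
#' and returns the whitespace-trimmed string at `answer_key`. Raises a
#' `bterag_parse_error` when no object parses, the key is absent, or the
#' value is not a scalar string ([run_item()] records that as a failure
#' instead of raising).
#'
#' @param raw_text backend reply.
#' @param answer_key key to extract.
#' @return the answer string.
#' @export
parse_answer <- function(raw_text, answer_key) {
  fail <- function(msg) {
    stop(structure(
      class = c("bterag_parse_error", "error", "condition"),
      list(message = msg, call = NULL)
    ))
  }
  obj_text <- extract_first_json_object(raw_text)
  if (is.null(obj_text)) fail("no JSON object found in reply")
  obj <- tryCatch(jsonlite::fromJSON(obj_text, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(obj) || !is.list(obj)) fail("reply object failed to parse")
  val <- obj[[answer_key]]
  if (is.null(val)) fail(sprintf("key '%s' absent from reply object", answer_key))
  if (!is.character(val) || length(val) != 1L) fail("answer value is not a scalar string")
  trimws(val)
}

#' Zero-shot drug/disease entity extraction
#'
#' Issues the extraction prompt to `backend` and parses the structured reply
#' into the drug and disease mentions. Benchmark runs bypass this step: items
#' carry pre-annotated, standardized knowledge-graph identifiers.
#'
#' @param question free-text question.
#' @param backend a generation backend (see [run_item()]).
#' @param templates a `prompt_templates` set.
#' @return list with `drug` and `disease` strings.
#' @export
extract_entities <- function(question, backend,
                             templates = default_prompt_templates()) {
  bundle <- structure(
    list(system_text = templates$extract, user_text = question, mode = "llm_only"),
    class = "prompt_bundle"
  )
  config <- make_generation_config(answer_key = "drug")
  raw <- backend$generate(bundle, config)
  drug <- tryCatch(parse_answer(raw, "drug"), bterag_parse_error = function(e) NULL)
  disease <- tryCatch(parse_answer(raw, "disease"), bterag_parse_error = function(e) NULL)
  if (is.null(drug) || is.null(disease)) {
    stop(sprintf("entity extraction failed; raw reply: %s", raw), call. = FALSE)
  }
  list(drug = drug, disease = disease)
}

#' Run one item through a generation backend
#'
#' Assembles the mode-appropriate prompt (LLM-only when `statements` is
#' `NULL`, retrieval-augmented otherwise), invokes the backend once, and
#' parses the structured answer. Backend and parse failures are recorded
#' (`parse_ok = FALSE`, empty answer) rather than raised, so a run continues
#' past bad items.
#'
#' @param item a `qa_item`.
#' @param backend backend object: `list(id, generate = function(bundle,
#'   config) -> text)`; see [make_scripted_backend()] for the offline one.
#' @param statements `NULL` (LLM-only) or a list of statements (bte_rag).
#' @param config a `generation_config`.
#' @param templates a `prompt_templates` set.
#' @return an `answer_record`: item_id, mode, raw_text, answer, parse_ok,
#'   n_context_statements.
#' @export
run_item <- function(item, backend, statements = NULL,
                     config = make_generation_config(default_answer_keys()[[item$benchmark]]),
                     templates = default_prompt_templates()) {
  mode <- if (is.null(statements)) "llm_only" else "bte_rag"
  bundle <- assemble_prompt(item, statements, mode, templates,
                            answer_key = config$answer_key)
  raw <- tryCatch(backend$generate(bundle, config), error = function(e) {
    paste0("<backend-error> ", conditionMessage(e))
  })
  ans <- tryCatch(parse_answer(raw, config$answer_key),
                  bterag_parse_error = function(e) NULL)
  structure(
    list(
      item_id = item$item_id,
      mode = mode,
      raw_text = raw,
      answer = if (is.null(ans)) "" else ans,
      parse_ok = !is.null(ans),
      n_context_statements = if (mode == "llm_only") 0L else length(statements)
    ),
    class = "answer_record"
  )
}

#' Write answer records as JSON Lines
#'
#' @param records list of `answer_record`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_answer_records <- function(records, path) {
  write_jsonl(lapply(records, unclass), path)
}

#' Read answer records from JSON Lines
#'
#' @param path file written by [write_answer_records()].
#' @return list of `answer_record`s.
#' @export
read_answer_records <- function(path) {
  lapply(read_jsonl(path), function(r) {
    structure(
      list(item_id = r$item_id, mode = r$mode, raw_text = r$raw_text,
           answer = r$answer %||% "", parse_ok = isTRUE(r$parse_ok),
           n_context_statements = as.integer(r$n_context_statements)),
      class = "answer_record"
    )
  })
}
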