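# TRAPI query construction, response parsing, and verbalization of
# knowledge-graph edges into provenance-annotated context statements.
#
# Only one-hop query graphs are produced: a pinned subject node (ids +
# category) connected to a free object node constrained by category. This is
# the shape a meta-knowledge-graph federator answers at its /v1/query
# endpoint.

#' Build a one-hop TRAPI query message
#'
#' @param subject_curie pinned entity identifier (CURIE).
#' @param subject_category Biolink category of the pinned node.
#' @param object_category Biolink category requested for the free node.
#' @param predicate optional Biolink predicate constraint for the edge.
#' @return a nested list representing the TRAPI request message.
#' @export
build_query <- function(subject_curie, subject_category, object_category,
                        predicate = NULL) {
  if (length(subject_curie) != 1L || !is_curie(subject_curie)) {
    stop(sprintf("invalid subject CURIE: '%s'", paste(subject_curie, collapse = ",")),
         call. = FALSE)
  }
  if (!nzchar(subject_category) || !nzchar(object_category)) {
    stop("subject and object categories must be non-empty", call. = FALSE)
  }
  edge <- list(subject = "n0", object = "n1")
  if (!is.null(predicate)) edge$predicates <- list(predicate)
  list(
    message = list(
      query_graph = list(
        nodes = list(
          n0 = list(ids = list(subject_curie), categories = list(subject_category)),
          n1 = list(categories = list(object_category))
        ),
        edges = list(e0 = edge)
      )
    )
  )
}

#' Serialize a TRAPI message to canonical JSON
#'
#' Identical inputs serialize to identical bytes (stable key order, unboxed
#' scalars), so serializations can key response caches.
#'
#' @param message TRAPI request or response message (nested list).
#' @return single JSON string.
#' @export
serialize_trapi <- function(message) {
  as.character(jsonlite::toJSON(message, auto_unbox = TRUE, null = "null",
                                digits = NA))
}

#' Parse a serialized TRAPI query back to its components
#'
#' Inverse of [build_query()] + [serialize_trapi()] for round-trip checks.
#'
#' @param json JSON string or parsed list.
#' @return list with `subject_curie`, `subject_category`, `object_category`,
#'   `predicate` (NULL when unconstrained).
#' @export
parse_query <- function(json) {
  msg <- if (is.character(json)) jsonlite::fromJSON(json, simplifyVector = FALSE) else json
  qg <- msg$message$query_graph
  if (is.null(qg)) stop("not a TRAPI query: missing message.query_graph", call. = FALSE)
  pinned <- Filter(function(n) !is.null(n$ids), qg$nodes)
  free <- Filter(function(n) is.null(n$ids), qg$nodes)
  if (length(pinned) != 1L || length(free) != 1L) {
    stop("expected exactly one pinned and one free query node", call. = FALSE)
  }
  preds <- qg$edges[[1]]$predicates
  list(
    subject_curie = pinned[[1]]$ids[[1]],
    subject_category = pinned[[1]]$categories[[1]],
    object_category = free[[1]]$categories[[1]],
    predicate = if (length(preds)) preds[[1]] else NULL
  )
}

#' Parse a TRAPI response knowledge graph
#'
#' Captures every node and edge of `message.knowledge_graph`. Node names fall
#' back to the CURIE when absent. Edges whose endpoints are missing from the
#' node index are dropped with a warning. Edge provenance keeps
#' `primary_knowledge_source` resource ids when the response annotates roles,
#' otherwise all listed resource ids.
#'
#' @param message TRAPI response (nested list or JSON string).
#' @return list with `nodes` (named list of `list(curie, name, categories)`)
#'   and `edges` (list of `list(subject_curie, predicate, object_curie,
#'   sources)`).
#' @export
parse_response <- function(message) {
  if (is.character(message)) message <- jsonlite::fromJSON(message, simplifyVector = FALSE)
  kg <- message$message$knowledge_graph %||% message$knowledge_graph
  if (is.null(kg)) stop("TRAPI response has no knowledge_graph section", call. = FALSE)

  nodes <- list()
  for (curie in names(kg$nodes %||% list())) {
    nd <- kg$nodes[[curie]]
    nodes[[curie]] <- list(
      curie = curie,
      name = if (is.null(nd$name) || !nzchar(nd$name)) curie else nd$name,
      categories = as.character(unlist(nd$categories))
    )
  }
  edges <- list()
  for (eid in names(kg$edges %||% list())) {
    ed <- kg$edges[[eid]]
    if (is.null(nodes[[ed$subject]]) || is.null(nodes[[ed$object]])) {
      warning(sprintf("dropping edge '%s': endpoint missing from node index", eid),
              call. = FALSE)
      next
    }
    edges[[length(edges) + 1L]] <- list(
      subject_curie = ed$subject,
      predicate = ed$predicate,
      object_curie = ed$object,
      sources = edge_sources(ed)
    )
  }
  list(nodes = nodes, edges = edges)
}

edge_sources <- function(edge) {
  src <- edge$sources
  if (is.null(src)) return(character(0))
  if (is.character(src)) return(src)
  ids <- vapply(src, function(s) as.character(s$resource_id %||% ""), character(1))
  roles <- vapply(src, function(s) as.character(s$resource_role %||% ""), character(1))
  primary <- ids[roles == "primary_knowledge_source" & nzchar(ids)]
  if (length(primary)) primary else ids[nzchar(ids)]
}

humanize_predicate <- function(predicate) {
  gsub("_", " ", sub("^biolink:", "", predicate), fixed = TRUE)
}

statement_text <- function(subject_name, predicate, object_name, sources) {
  base <- paste(subject_name, humanize_predicate(predicate), object_name)
  if (length(sources)) {
    paste0(base, " (source: ", paste(sources, collapse = ", "), ")")
  } else {
    base
  }
}

new_context_statement <- function(text, subject_curie, predicate, object_curie,
                                  sources, origin_query = NA_character_) {
  structure(
    list(text = text, subject_curie = subject_curie, predicate = predicate,
         object_curie = object_curie, sources = sources,
         origin_query = origin_query),
    class = "context_statement"
  )
}

#' Verbalize knowledge-graph edges into context statements
#'
#' Each edge becomes one declarative sentence, subject name first, then the
#' humanized predicate (the `biolink:` prefix stripped and underscores
#' replaced by spaces), then the object name, followed by a provenance suffix
#' `" (source: ...)"` listing the primary knowledge sources. Output order is
#' input edge order. Entity names fall back to CURIEs when the node index
#' carries no label.
#'
#' @param edges list of parsed edges (see [parse_response()]).
#' @param node_index named list of parsed nodes covering all edge endpoints.
#' @param origin_query optional label of the query-plan slot that produced
#'   these edges.
#' @return list of `context_statement`s.
#' @export
verbalize <- function(edges, node_index, origin_query = NA_character_) {
  lapply(edges, function(ed) {
    sn <- node_index[[ed$subject_curie]]$name %||% ed$subject_curie
    on <- node_index[[ed$object_curie]]$name %||% ed$object_curie
    new_context_statement(
      text = statement_text(sn, ed$predicate, on, ed$sources),
      subject_curie = ed$subject_curie,
      predicate = ed$predicate,
      object_curie = ed$object_curie,
      sources = ed$sources,
      origin_query = origin_query
    )
  })
}

# Per-benchmark retrieval plans. Each slot pins one anchor entity of the item
# and asks for one free output category; slots are issued in this order.
retrieval_plan <- function(item) {
  switch(item$benchmark,
    gene = list(
      list(slot = "disease->Gene",    subject = item$disease_curie, subject_category = "biolink:Disease", object_category = "biolink:Gene"),
      list(slot = "disease->Protein", subject = item$disease_curie, subject_category = "biolink:Disease", object_category = "biolink:Protein"),
      list(slot = "drug->Gene",       subject = item$drug_curie,    subject_category = "biolink:Drug",    object_category = "biolink:Gene"),
      list(slot = "drug->Protein",    subject = item$drug_curie,    subject_category = "biolink:Drug",    object_category = "biolink:Protein")
    ),
    metabolite = list(
      list(slot = "disease->ChemicalEntity", subject = item$disease_curie, subject_category = "biolink:Disease", object_category = "biolink:ChemicalEntity"),
      list(slot = "drug->ChemicalEntity",    subject = item$drug_curie,    subject_category = "biolink:Drug",    object_category = "biolink:ChemicalEntity")
    ),
    drug = list(
      list(slot = "disease->ChemicalEntity", subject = item$disease_curie, subject_category = "biolink:Disease",           object_category = "biolink:ChemicalEntity"),
      list(slot = "process->ChemicalEntity", subject = item$anchor_curie,  subject_category = "biolink:BiologicalProcess", object_category = "biolink:ChemicalEntity")
    ),
    stop(sprintf("unknown benchmark kind '%s'", item$benchmark), call. = FALSE)
  )
}

#' Retrieve and verbalize knowledge-graph context for one QA item
#'
#' Executes the item's benchmark-specific query plan against `transport` (a
#' callable mapping a TRAPI request to a TRAPI response), verbalizes each
#' slot's edges, and concatenates statements in plan order. Identical
#' (subject, predicate, object) triples returned by several slots are
#' de-duplicated keeping the first occurrence with sources unioned. A failing
#' slot is skipped with a warning; if every slot fails, retrieval errors.
#'
#' @param item a `qa_item`.
#' @param transport function(request) -> TRAPI response (list or JSON string).
#' @param cache_dir optional directory; responses are cached as JSON keyed by
#'   a hash of the serialized request, making runs replay-identical.
#' @return list of `context_statement`s (possibly empty).
#' @export
retrieve_for_item <- function(item, transport, cache_dir = NULL) {
  plan <- retrieval_plan(item)
  statements <- list()
  failures <- 0L
  for (slot in plan) {
    req <- build_query(slot$subject, slot$subject_category, slot$object_category)
    resp <- tryCatch(
      transport_with_cache(req, transport, cache_dir),
      error = function(e) {
        warning(sprintf("retrieval slot '%s' failed for item %s: %s",
                        slot$slot, item$item_id, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(resp)) {
      failures <- failures + 1L
      next
    }
    parsed <- parse_response(resp)
    statements <- c(statements, verbalize(parsed$edges, parsed$nodes, slot$slot))
  }
  if (failures == length(plan) && length(plan) > 0L) {
    stop(sprintf("all retrieval slots failed for item %s", item$item_id),
         call. = FALSE)
  }
  dedup_statements(statements)
}

transport_with_cache <- function(req, transport, cache_dir) {
  if (is.null(cache_dir)) return(transport(req))
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  key <- stable_hash(serialize_trapi(req))
  path <- file.path(cache_dir, paste0(key, ".json"))
  if (file.exists(path)) {
    return(jsonlite::fromJSON(path, simplifyVector = FALSE))
  }
  resp <- transport(req)
  if (is.character(resp)) resp <- jsonlite::fromJSON(resp, simplifyVector = FALSE)
  writeLines(serialize_trapi(resp), path, useBytes = TRUE)
  resp
}

# First occurrence per (subject, predicate, object) kept; sources unioned and
# the provenance suffix re-rendered from the union.
dedup_statements <- function(statements) {
  if (!length(statements)) return(list())
  keys <- vapply(statements, function(s)
    paste(s$subject_curie, s$predicate, s$object_curie, sep = "\x01"), character(1))
  out <- list()
  order_keys <- character(0)
  for (i in seq_along(statements)) {
    k <- keys[[i]]
    if (is.null(out[[k]])) {
      out[[k]] <- statements[[i]]
      order_keys <- c(order_keys, k)
    } else {
      merged <- union(out[[k]]$sources, statements[[i]]$sources)
      if (!identical(merged, out[[k]]$sources)) {
        s <- out[[k]]
        s$sources <- merged
        # strip the old provenance suffix, re-render with the unioned sources
        base <- sub(" \\(source: [^)]*\\)$", "", s$text)
        s$text <- if (length(merged)) {
          paste0(base, " (source: ", paste(merged, collapse = ", "), ")")
        } else {
          base
        }
        out[[k]] <- s
      }
    }
  }
  unname(out[order_keys])
}

#' Export context statements as JSON Lines
#'
#' @param statements list of `context_statement`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_statements <- function(statements, path) {
  recs <- lapply(statements, function(s) {
    list(text = s$text,
         triple = list(subject = s$subject_curie, predicate = s$predicate,
                       object = s$object_curie),
         sources = as.list(s$sources),
         origin_query = s$origin_query)
  })
  write_jsonl(recs, path)
}
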