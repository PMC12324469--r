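# Parsing of mechanism-path corpora and construction of the three QA
# benchmarks (gene-, metabolite- and drug-centric).
#
# A mechanism record describes one indication (drug--disease pairing) as a
# small typed graph: an ordered node list from the drug to the disease through
# biologically meaningful intermediates, and predicate-labelled edges.

#' Default label-to-Biolink-category mapping
#'
#' Corpus node labels are short type names (`"Gene"`, `"Protein"`, ...); the
#' builders operate on fully-qualified Biolink category strings. Labels absent
#' from the table are passed through with a `biolink:` prefix.
#'
#' @return named character vector mapping label to Biolink category.
#' @export
default_category_map <- function() {
  c(
    Drug              = "biolink:Drug",
    Gene              = "biolink:Gene",
    Protein           = "biolink:Protein",
    GeneFamily        = "biolink:GeneFamily",
    Disease           = "biolink:Disease",
    BiologicalProcess = "biolink:BiologicalProcess",
    ChemicalEntity    = "biolink:ChemicalEntity",
    ChemicalSubstance = "biolink:ChemicalEntity",
    MolecularActivity = "biolink:MolecularActivity",
    OrganismTaxon     = "biolink:OrganismTaxon",
    PhenotypicFeature = "biolink:PhenotypicFeature",
    CellularComponent = "biolink:CellularComponent",
    Pathway           = "biolink:Pathway",
    MacromolecularComplex = "biolink:MacromolecularComplex"
  )
}

map_category <- function(label, category_map = default_category_map()) {
  out <- unname(category_map[label])
  miss <- is.na(out)
  already <- miss & grepl("^biolink:", label)
  out[already] <- label[already]
  rest <- is.na(out)
  out[rest] <- paste0("biolink:", label[rest])
  out
}

new_mech_path <- function(indication_id, nodes, edges, drug_curie, disease_curie) {
  structure(
    list(
      indication_id = indication_id,
      nodes = nodes,   # data.frame: curie, name, category (ordered drug..disease)
      edges = edges,   # data.frame: subject, predicate, object
      drug_curie = drug_curie,
      disease_curie = disease_curie
    ),
    class = "mech_path"
  )
}

#' @export
print.mech_path <- function(x, ...) {
  cat(sprintf("<mech_path %s: %s -> %s, %d nodes, %d edges>\n",
              x$indication_id, x$drug_curie, x$disease_curie,
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Internal (intermediate) nodes: the ordered node list minus its endpoints.
internal_nodes <- function(path) {
  n <- nrow(path$nodes)
  if (n <= 2L) return(path$nodes[0L, , drop = FALSE])
  path$nodes[-c(1L, n), , drop = FALSE]
}

path_node_names <- function(path) {
  stats::setNames(path$nodes$name, path$nodes$curie)
}

#' Parse a mechanism-path corpus
#'
#' Accepts either a file path (YAML or JSON) or an already-deserialized list of
#' records. Each record has keys `graph` (indication metadata including the
#' drug and disease identifiers), `nodes` (`id`, `name`, `label`) and `links`
#' (`source`, `key`, `target`). Node `label`s are mapped to Biolink categories
#' via `category_map`. Node order in the record is preserved; the first node
#' must be the declared drug and the last the declared disease.
#'
#' @param records file path or list of record lists.
#' @param category_map label-to-category table, see [default_category_map()].
#' @return list of `mech_path` objects.
#' @export
parse_path_corpus <- function(records, category_map = default_category_map()) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_corpus_file(records)
  }
  stopifnot(is.list(records))
  lapply(records, parse_path_record, category_map = category_map)
}

read_corpus_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
}

parse_path_record <- function(record, category_map = default_category_map()) {
  known <- c("graph", "nodes", "links")
  extra <- setdiff(names(record), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown record keys: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  graph <- record$graph
  indication_id <- as.character(graph$`_id` %||% graph$id %||% "<unidentified>")
  drug_curie <- as.character(graph$drug %||% graph$drug_id %||% "")
  disease_curie <- as.character(graph$disease %||% graph$disease_id %||% "")

  nodes <- do.call(rbind, lapply(record$nodes, function(nd) {
    data.frame(
      curie = as.character(nd$id),
      name = as.character(nd$name %||% nd$id),
      category = map_category(as.character(nd$label), category_map),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(nodes) || nrow(nodes) < 2L) {
    stop(sprintf("malformed record '%s': fewer than 2 nodes", indication_id),
         call. = FALSE)
  }
  bad <- !is_curie(nodes$curie) | !nzchar(nodes$category)
  if (any(bad)) {
    stop(sprintf("malformed record '%s': invalid node identifier(s): %s",
                 indication_id, paste(nodes$curie[bad], collapse = ", ")),
         call. = FALSE)
  }
  if (!drug_curie %in% nodes$curie || !disease_curie %in% nodes$curie) {
    stop(sprintf(
      "malformed record '%s': declared drug/disease absent from node list",
      indication_id), call. = FALSE)
  }
  if (nodes$curie[1L] != drug_curie || nodes$curie[nrow(nodes)] != disease_curie) {
    stop(sprintf(
      "malformed record '%s': ordered node list must start at the drug and end at the disease",
      indication_id), call. = FALSE)
  }

  edges <- if (length(record$links)) {
    do.call(rbind, lapply(record$links, function(lk) {
      data.frame(
        subject = as.character(lk$source),
        predicate = as.character(lk$key),
        object = as.character(lk$target),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame(subject = character(0), predicate = character(0),
               object = character(0), stringsAsFactors = FALSE)
  }
  dangling <- !(edges$subject %in% nodes$curie) | !(edges$object %in% nodes$curie)
  if (any(dangling)) {
    stop(sprintf("malformed record '%s': edge endpoint not in node list",
                 indication_id), call. = FALSE)
  }
  new_mech_path(indication_id, nodes, edges, drug_curie, disease_curie)
}

# ---- QA items ---------------------------------------------------------------

new_qa_item <- function(benchmark, question, truth_label, truth_curie,
                        drug_curie, disease_curie, anchor_curie = "",
                        source_path_ids = character(0)) {
  key <- dedup_key(question, truth_label)
  structure(
    list(
      item_id = stable_hash(key),
      benchmark = benchmark,
      question = question,
      truth_label = truth_label,
      truth_curie = truth_curie,
      drug_curie = drug_curie,
      disease_curie = disease_curie,
      anchor_curie = anchor_curie,
      source_path_ids = as.character(source_path_ids)
    ),
    class = "qa_item"
  )
}

#' @export
print.qa_item <- function(x, ...) {
  cat(sprintf("<qa_item %s [%s] truth=%s>\n  %s\n",
              x$item_id, x$benchmark, x$truth_label, x$question))
  invisible(x)
}

# Deduplication key: normalized question wording plus upper-cased answer.
# Indications that share question text and ground truth collapse to one item.
dedup_key <- function(question, truth_label) {
  paste(tolower(squish(question)), toupper(truth_label), sep = "\x01")
}

# Question templates (configurable; these follow the benchmark's phrasing).
qa_templates <- function() {
  list(
    gene = "Which gene plays the most significant mechanistic role in how Drug '%s' treats or impacts Disease '%s'?",
    metabolite = "Which biochemical entity is affected by Drug '%s' via its mechanism of action in treating Disease '%s'?",
    drug = "Which drug can be used in the treatment of Disease '%s' by targeting Biological Process '%s'?"
  )
}

#' Deduplicate QA items
#'
#' One item is kept per deduplication key (normalized question text plus
#' upper-cased truth label); the first-seen item's fields are retained and the
#' `source_path_ids` of merged duplicates are unioned. Output order is
#' first-seen order. Idempotent.
#'
#' @param items list of `qa_item`s.
#' @return deduplicated list of `qa_item`s.
#' @export
deduplicate_items <- function(items) {
  if (!length(items)) return(list())
  keys <- vapply(items, function(it) dedup_key(it$question, it$truth_label),
                 character(1))
  out <- list()
  for (i in seq_along(items)) {
    k <- keys[[i]]
    if (is.null(out[[k]])) {
      out[[k]] <- items[[i]]
    } else {
      out[[k]]$source_path_ids <-
        union(out[[k]]$source_path_ids, items[[i]]$source_path_ids)
    }
  }
  unname(out)
}

#' Static identifier resolver
#'
#' Builds a resolver (CURIE to HGNC symbol) from a named character vector.
#' Identifiers absent from the map resolve to the sentinel `"not_found"`;
#' maps may also carry the sentinels `"ambiguous"` and `"deprecated"`, which
#' mark identifiers the gene benchmark must exclude.
#'
#' @param map named character vector, names are CURIEs.
#' @return function(curie) -> symbol or sentinel string.
#' @export
make_static_resolver <- function(map) {
  force(map)
  function(curie) {
    val <- unname(map[curie])
    if (is.na(val)) "not_found" else val
  }
}

resolver_sentinels <- c("ambiguous", "deprecated", "not_found")

#' Build the gene-centric benchmark
#'
#' Retains paths whose internal nodes contain exactly one `biolink:Gene` node
#' (Protein-category nodes do not qualify), resolves the gene identifier to an
#' HGNC symbol via `resolver`, and excludes paths whose identifier resolves to
#' a sentinel (`ambiguous` / `deprecated` / `not_found`). Questions follow the
#' gene template; the truth label is the resolved symbol. The result is
#' deduplicated across indications.
#'
#' @param paths list of `mech_path`s.
#' @param resolver function(curie) -> HGNC symbol or sentinel, see
#'   [make_static_resolver()].
#' @return list of `qa_item`s.
#' @export
build_gene_benchmark <- function(paths, resolver) {
  stopifnot(is.function(resolver))
  items <- list()
  for (p in paths) {
    inn <- internal_nodes(p)
    genes <- inn[inn$category == "biolink:Gene", , drop = FALSE]
    if (nrow(genes) != 1L) {
      log_event("gene_benchmark", "skip:not_exactly_one_gene", p$indication_id)
      next
    }
    symbol <- tryCatch(resolver(genes$curie), error = function(e) {
      log_event("gene_benchmark", "skip:resolver_failure",
                paste(p$indication_id, conditionMessage(e)))
      "not_found"
    })
    if (symbol %in% resolver_sentinels) {
      log_event("gene_benchmark", paste0("skip:", symbol), p$indication_id)
      next
    }
    nm <- path_node_names(p)
    question <- sprintf(qa_templates()$gene, nm[[p$drug_curie]], nm[[p$disease_curie]])
    items[[length(items) + 1L]] <- new_qa_item(
      benchmark = "gene", question = question,
      truth_label = symbol, truth_curie = genes$curie,
      drug_curie = p$drug_curie, disease_curie = p$disease_curie,
      source_path_ids = p$indication_id
    )
  }
  deduplicate_items(items)
}

#' Default taxonomic predicate set
#'
#' Predicates counted as taxonomic ("is-a"-style) when dropping paths that
#' consist exclusively of taxonomic relationships. Matching is case-insensitive
#' and ignores the `biolink:` prefix.
#' @return character vector.
#' @export
default_taxonomic_predicates <- function() {
  c("biolink:subclass_of", "subclass")
}

is_taxonomic <- function(predicate, taxonomic_predicates) {
  norm <- function(x) tolower(sub("^biolink:", "", x))
  norm(predicate) %in% norm(taxonomic_predicates)
}

#' Build the metabolite-centric benchmark
#'
#' Drops paths whose every edge predicate is taxonomic (e.g. "subclass"),
#' retains paths with exactly one internal node in the `CHEBI:` namespace, and
#' drops any drug--disease indication represented by more than one qualifying
#' path. Questions follow the metabolite template; the truth is the CHEBI
#' node's name and identifier. Deduplicated across indications.
#'
#' @param paths list of `mech_path`s.
#' @param taxonomic_predicates predicates treated as taxonomic.
#' @return list of `qa_item`s.
#' @export
build_metabolite_benchmark <- function(paths,
                                       taxonomic_predicates = default_taxonomic_predicates()) {
  qualifying <- list()
  for (p in paths) {
    if (nrow(p$edges) > 0L &&
        all(is_taxonomic(p$edges$predicate, taxonomic_predicates))) {
      log_event("metabolite_benchmark", "skip:all_taxonomic", p$indication_id)
      next
    }
    inn <- internal_nodes(p)
    chebi <- inn[!is.na(curie_prefix(inn$curie)) & curie_prefix(inn$curie) == "chebi", ,
                 drop = FALSE]
    if (nrow(chebi) != 1L) {
      log_event("metabolite_benchmark", "skip:not_exactly_one_chebi", p$indication_id)
      next
    }
    qualifying[[length(qualifying) + 1L]] <- list(path = p, metabolite = chebi)
  }
  # one qualifying path per indication; multiples are excluded outright
  ind <- vapply(qualifying, function(q)
    paste(q$path$drug_curie, q$path$disease_curie, sep = "\x01"), character(1))
  multi <- names(which(table(ind) > 1L))
  items <- list()
  for (i in seq_along(qualifying)) {
    if (ind[[i]] %in% multi) {
      log_event("metabolite_benchmark", "skip:multiple_paths_per_indication",
                qualifying[[i]]$path$indication_id)
      next
    }
    p <- qualifying[[i]]$path
    met <- qualifying[[i]]$metabolite
    nm <- path_node_names(p)
    question <- sprintf(qa_templates()$metabolite, nm[[p$drug_curie]], nm[[p$disease_curie]])
    items[[length(items) + 1L]] <- new_qa_item(
      benchmark = "metabolite", question = question,
      truth_label = met$name, truth_curie = met$curie,
      drug_curie = p$drug_curie, disease_curie = p$disease_curie,
      source_path_ids = p$indication_id
    )
  }
  deduplicate_items(items)
}

#' Build the drug-centric benchmark
#'
#' Retains paths containing exactly one `biolink:BiologicalProcess` node and a
#' drug identifier in the DrugBank or MeSH namespace (others lack a resolvable
#' standardized identifier and are excluded). Questions follow the drug
#' template, anchored on the disease and the mediating biological process; the
#' truth is the drug's name and identifier. Deduplicated across indications.
#'
#' @param paths list of `mech_path`s.
#' @param drug_namespaces lower-cased namespace prefixes accepted for the drug.
#' @return list of `qa_item`s.
#' @export
build_drug_benchmark <- function(paths, drug_namespaces = c("drugbank", "mesh", "db")) {
  items <- list()
  for (p in paths) {
    proc <- p$nodes[p$nodes$category == "biolink:BiologicalProcess", , drop = FALSE]
    if (nrow(proc) != 1L) {
      log_event("drug_benchmark", "skip:not_exactly_one_process", p$indication_id)
      next
    }
    if (!(curie_prefix(p$drug_curie) %in% tolower(drug_namespaces))) {
      log_event("drug_benchmark", "skip:unresolvable_drug_namespace", p$indication_id)
      next
    }
    nm <- path_node_names(p)
    question <- sprintf(qa_templates()$drug, nm[[p$disease_curie]], proc$name)
    items[[length(items) + 1L]] <- new_qa_item(
      benchmark = "drug", question = question,
      truth_label = nm[[p$drug_curie]], truth_curie = p$drug_curie,
      drug_curie = p$drug_curie, disease_curie = p$disease_curie,
      anchor_curie = proc$curie,
      source_path_ids = p$indication_id
    )
  }
  deduplicate_items(items)
}

#' Write QA items as JSON Lines
#'
#' One item per line with keys exactly: item_id, benchmark, question,
#' truth_label, truth_curie, drug_curie, disease_curie, anchor_curie,
#' source_path_ids.
#'
#' @param items list of `qa_item`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(items, path) {
  recs <- lapply(items, function(it) {
    list(
      item_id = it$item_id, benchmark = it$benchmark, question = it$question,
      truth_label = it$truth_label, truth_curie = it$truth_curie,
      drug_curie = it$drug_curie, disease_curie = it$disease_curie,
      anchor_curie = it$anchor_curie,
      source_path_ids = as.list(it$source_path_ids)
    )
  })
  write_jsonl(recs, path)
}

#' Read QA items from a JSON Lines benchmark file
#'
#' @param path benchmark file written by [write_benchmark()].
#' @return list of `qa_item`s.
#' @export
read_benchmark <- function(path) {
  lapply(read_jsonl(path), function(r) {
    structure(
      list(
        item_id = r$item_id, benchmark = r$benchmark, question = r$question,
        truth_label = r$truth_label, truth_curie = r$truth_curie,
        drug_curie = r$drug_curie, disease_curie = r$disease_curie,
        anchor_curie = r$anchor_curie %||% "",
        source_path_ids = as.character(unlist(r$source_path_ids))
      ),
      class = "qa_item"
    )
  })
}
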