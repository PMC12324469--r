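# Shared in-code fixtures: tiny corpus records, QA items, statements and a
# canned TRAPI response. Everything is built programmatically; no data files.

tiny_record <- function(id = "IND1",
                        drug = list(id = "MESH:D000001", name = "DrugA", label = "Drug"),
                        internals = list(list(id = "NCBIGene:1", name = "GENE1", label = "Gene")),
                        disease = list(id = "MONDO:0000001", name = "DisD", label = "Disease"),
                        predicates = NULL) {
  nodes <- c(list(drug), internals, list(disease))
  if (is.null(predicates)) predicates <- rep("biolink:affects", length(nodes) - 1L)
  links <- lapply(seq_len(length(nodes) - 1L), function(i) {
    list(source = nodes[[i]]$id, key = predicates[i], target = nodes[[i + 1L]]$id)
  })
  list(graph = list(`_id` = id, drug = drug$id, disease = disease$id),
       nodes = nodes, links = links)
}

tiny_item <- function(benchmark = "gene",
                      question = "Which gene plays the most significant mechanistic role in how Drug 'DrugA' treats or impacts Disease 'DisD'?",
                      truth_label = "GENE1", truth_curie = "NCBIGene:1",
                      drug_curie = "MESH:D000001", disease_curie = "MONDO:0000001",
                      anchor_curie = "") {
  structure(
    list(item_id = bterag::stable_hash(paste(question, truth_label)),
         benchmark = benchmark, question = question, truth_label = truth_label,
         truth_curie = truth_curie, drug_curie = drug_curie,
         disease_curie = disease_curie, anchor_curie = anchor_curie,
         source_path_ids = "IND1"),
    class = "qa_item"
  )
}

tiny_statement <- function(text, subject = "S:1", predicate = "biolink:affects",
                           object = "O:1", sources = "ctd") {
  structure(
    list(text = text, subject_curie = subject, predicate = predicate,
         object_curie = object, sources = sources, origin_query = "test"),
    class = "context_statement"
  )
}

# Minimal schema-valid TRAPI response: 2 nodes, 1 edge, 1 primary source.
tiny_trapi_response <- function() {
  list(message = list(knowledge_graph = list(
    nodes = list(
      "MESH:D000001" = list(name = "drug X", categories = list("biolink:Drug")),
      "NCBIGene:1" = list(name = "gene Y", categories = list("biolink:Gene"))
    ),
    edges = list(
      e0 = list(subject = "MESH:D000001", predicate = "biolink:inhibits",
                object = "NCBIGene:1",
                sources = list(list(resource_id = "ctd",
                                    resource_role = "primary_knowledge_source")))
    )
  )))
}

# Brute-force percentile-filter oracle: score every statement, sort all
# (score, position) pairs, drop the bottom k = floor(p * n / 100) with later
# positions yielding first among ties, keep survivors in original order.
oracle_percentile_filter <- function(scores, p) {
  n <- length(scores)
  k <- floor(p * n / 100)
  if (n == 0L || k == 0L) return(seq_len(n))
  pairs <- data.frame(score = scores, pos = seq_len(n))
  pairs <- pairs[order(pairs$score, -pairs$pos), ]
  dropped <- pairs$pos[seq_len(k)]
  sort(setdiff(seq_len(n), dropped))
}

scored_fixture <- function(scores) {
  lapply(seq_along(scores), function(i) {
    structure(list(statement = tiny_statement(sprintf("stmt %d", i)),
                   score = scores[i]),
              class = "scored_statement")
  })
}
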