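# Corpus parsing and benchmark construction.

test_that("parse_path_corpus parses well-formed records and preserves order", {
  rec <- tiny_record(predicates = c("biolink:inhibits", "biolink:causes"))
  paths <- parse_path_corpus(list(rec))
  expect_length(paths, 1)
  p <- paths[[1]]
  expect_s3_class(p, "mech_path")
  expect_equal(p$nodes$curie, c("MESH:D000001", "NCBIGene:1", "MONDO:0000001"))
  expect_equal(p$nodes$category,
               c("biolink:Drug", "biolink:Gene", "biolink:Disease"))
  expect_equal(p$edges$predicate, c("biolink:inhibits", "biolink:causes"))
  expect_equal(nrow(bterag:::internal_nodes(p)), 1)
  expect_equal(parse_path_corpus(list()), list())
})

test_that("parse_path_corpus reads YAML and JSON files identically", {
  recs <- list(tiny_record("IND1"), tiny_record("IND2",
    drug = list(id = "MESH:D000002", name = "DrugB", label = "Drug"),
    disease = list(id = "MONDO:0000002", name = "DisE", label = "Disease")))
  yml <- withr::local_tempfile(fileext = ".yaml")
  jsn <- withr::local_tempfile(fileext = ".json")
  yaml::write_yaml(recs, yml)
  writeLines(as.character(jsonlite::toJSON(recs, auto_unbox = TRUE)), jsn)
  expect_equal(parse_path_corpus(yml), parse_path_corpus(jsn))
})

test_that("malformed records error with the indication id", {
  rec <- tiny_record("BADREC")
  rec$nodes <- rev(rec$nodes)  # disease first, drug last
  expect_error(parse_path_corpus(list(rec)), "BADREC")

  rec2 <- tiny_record("NODRUG")
  rec2$graph$drug <- "MESH:D999999"  # declared drug absent from node list
  expect_error(parse_path_corpus(list(rec2)), "NODRUG")

  rec3 <- tiny_record("EXTRAKEY")
  rec3$unexpected <- "x"
  expect_warning(parse_path_corpus(list(rec3)), "unknown record keys")
})

test_that("gene benchmark keeps exactly-one-internal-Gene paths and excludes sentinels", {
  one_gene <- tiny_record("G1")
  two_genes <- tiny_record("G2", internals = list(
    list(id = "NCBIGene:2", name = "GENE2", label = "Gene"),
    list(id = "NCBIGene:3", name = "GENE3", label = "Gene")))
  no_gene <- tiny_record("G3", internals = list(
    list(id = "UniProtKB:P1", name = "prot", label = "Protein")))
  paths <- parse_path_corpus(list(one_gene, two_genes, no_gene))
  resolver <- make_static_resolver(c("NCBIGene:1" = "GENE1",
                                     "NCBIGene:2" = "GENE2",
                                     "NCBIGene:3" = "GENE3"))
  items <- build_gene_benchmark(paths, resolver)
  expect_length(items, 1)
  expect_equal(items[[1]]$truth_label, "GENE1")
  expect_match(items[[1]]$question,
               "^Which gene plays the most significant mechanistic role in how Drug")
  expect_match(items[[1]]$question, "DrugA", fixed = TRUE)
  expect_match(items[[1]]$question, "DisD", fixed = TRUE)

  # deprecated/ambiguous/not_found identifiers are all excluded
  for (sentinel in c("ambiguous", "deprecated", "not_found")) {
    bad <- make_static_resolver(c("NCBIGene:1" = sentinel))
    expect_length(build_gene_benchmark(paths[1], bad), 0)
  }
})

test_that("Protein-category internal nodes do not satisfy the gene filter", {
  rec <- tiny_record("GP", internals = list(
    list(id = "NCBIGene:1", name = "GENE1", label = "Gene"),
    list(id = "UniProtKB:P1", name = "gene1 protein", label = "Protein")))
  paths <- parse_path_corpus(list(rec))
  items <- build_gene_benchmark(paths, make_static_resolver(c("NCBIGene:1" = "GENE1")))
  expect_length(items, 1)  # the Protein node does not make it two "genes"
})

test_that("metabolite benchmark applies all three filters", {
  met <- function(id, drug_id, dis_id, chebi, preds = NULL) {
    tiny_record(id,
      drug = list(id = drug_id, name = paste0("Drug", id), label = "Drug"),
      internals = list(list(id = chebi, name = paste0("met", id), label = "ChemicalEntity")),
      disease = list(id = dis_id, name = paste0("Dis", id), label = "Disease"),
      predicates = preds)
  }
  taxo <- met("T1", "MESH:D1", "MONDO:1", "CHEBI:10",
              preds = c("biolink:subclass_of", "subclass"))
  # two qualifying paths sharing one indication: both excluded
  dupA <- met("D-A", "MESH:D2", "MONDO:2", "CHEBI:11")
  dupB <- met("D-B", "MESH:D2", "MONDO:2", "CHEBI:12")
  okA <- met("OK1", "MESH:D3", "MONDO:3", "CHEBI:13")
  okB <- met("OK2", "MESH:D4", "MONDO:4", "chebi:14")  # prefix case-insensitive
  paths <- parse_path_corpus(list(taxo, dupA, dupB, okA, okB))
  items <- build_metabolite_benchmark(paths)
  expect_length(items, 2)
  expect_setequal(vapply(items, `[[`, character(1), "truth_curie"),
                  c("CHEBI:13", "chebi:14"))
  expect_match(items[[1]]$question, "^Which biochemical entity is affected by Drug")
})

test_that("drug benchmark requires one process node and a resolvable namespace", {
  proc <- list(id = "GO:0001", name = "regulation of x", label = "BiologicalProcess")
  ok_db <- tiny_record("P1",
    drug = list(id = "DB00945", name = "Aspirinib", label = "Drug"),
    internals = list(proc))
  ok_mesh <- tiny_record("P2",
    drug = list(id = "MESH:D900001", name = "Meshol", label = "Drug"),
    internals = list(list(id = "GO:0002", name = "regulation of y",
                          label = "BiologicalProcess")))
  bad_ns <- tiny_record("P3",
    drug = list(id = "UNII:XYZ", name = "Uniiol", label = "Drug"),
    internals = list(list(id = "GO:0003", name = "regulation of z",
                          label = "BiologicalProcess")))
  two_proc <- tiny_record("P4",
    drug = list(id = "DB00946", name = "Dupline", label = "Drug"),
    internals = list(list(id = "GO:0004", name = "proc a", label = "BiologicalProcess"),
                     list(id = "GO:0005", name = "proc b", label = "BiologicalProcess")))
  items <- build_drug_benchmark(parse_path_corpus(list(ok_db, ok_mesh, bad_ns, two_proc)))
  expect_length(items, 2)
  it <- items[[1]]
  expect_equal(it$truth_curie, "DB00945")
  expect_equal(it$anchor_curie, "GO:0001")
  expect_match(it$question, "^Which drug can be used in the treatment of Disease")
  # anchor_curie is non-empty exactly for the drug benchmark
  expect_true(all(nzchar(vapply(items, `[[`, character(1), "anchor_curie"))))
})

test_that("deduplicate_items merges on question+truth and is idempotent", {
  a <- tiny_item(); a$source_path_ids <- "IND1"
  b <- tiny_item(); b$source_path_ids <- "IND2"
  c2 <- tiny_item(truth_label = "OTHER1")
  out <- deduplicate_items(list(a, b, c2))
  expect_length(out, 2)
  expect_setequal(out[[1]]$source_path_ids, c("IND1", "IND2"))
  expect_identical(deduplicate_items(out), out)
  expect_equal(deduplicate_items(list()), list())
})

test_that("builder output is input-order independent and truth curies trace to sources", {
  corpus <- generate_corpus(corpus_config(n_gene_paths = 15, n_metabolite_paths = 15,
                                          n_process_paths = 10, n_decoy_paths = 10,
                                          n_multigene_paths = 5, seed = 17))
  paths <- parse_path_corpus(corpus$records)
  resolver <- make_static_resolver(corpus$resolver_map)
  build_all <- function(ps) {
    list(g = build_gene_benchmark(ps, resolver),
         m = build_metabolite_benchmark(ps),
         d = build_drug_benchmark(ps))
  }
  normalize <- function(items) items[order(vapply(items, `[[`, character(1), "item_id"))]
  straight <- build_all(paths)
  shuffled <- build_all(withr::with_seed(99, sample(paths)))
  for (b in names(straight)) {
    expect_identical(normalize(straight[[b]]), normalize(shuffled[[b]]))
  }
  # every item's truth curie appears as a node in one of its source paths
  path_by_id <- setNames(paths, vapply(paths, `[[`, character(1), "indication_id"))
  for (items in straight) {
    for (it in items) {
      hits <- vapply(it$source_path_ids, function(pid)
        it$truth_curie %in% path_by_id[[pid]]$nodes$curie, logical(1))
      expect_true(any(hits))
    }
  }
})

test_that("benchmark JSONL round-trips with the exact key set", {
  items <- list(tiny_item(), tiny_item(truth_label = "OTHER1"))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_benchmark(items, f)
  raw <- jsonlite::fromJSON(readLines(f)[1], simplifyVector = FALSE)
  expect_identical(names(raw),
                   c("item_id", "benchmark", "question", "truth_label",
                     "truth_curie", "drug_curie", "disease_curie",
                     "anchor_curie", "source_path_ids"))
  back <- read_benchmark(f)
  expect_equal(back, items)
})
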