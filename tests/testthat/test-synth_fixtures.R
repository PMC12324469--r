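# The seeded synthetic world: corpora, transports, embedder, backend.

small_config <- corpus_config(n_gene_paths = 8, n_metabolite_paths = 6,
                              n_process_paths = 5, n_decoy_paths = 5,
                              n_multigene_paths = 2, seed = 101)

test_that("generate_corpus is deterministic and honours the configured counts", {
  c1 <- generate_corpus(small_config)
  c2 <- generate_corpus(small_config)
  expect_identical(c1, c2)
  # byte-identical serialized form
  expect_identical(serialize(c1$records, NULL), serialize(c2$records, NULL))
  kinds <- table(vapply(c1$registry, `[[`, character(1), "benchmark"))
  expect_equal(unname(kinds[["gene"]]), 8)
  expect_equal(unname(kinds[["metabolite"]]), 6)
  expect_equal(unname(kinds[["drug"]]), 5)
  empty <- generate_corpus(corpus_config(0, 0, 0, 0, 0, seed = 1))
  expect_length(empty$records, 0)
  expect_length(empty$registry, 0)
})

test_that("generated records parse and every registry truth is reachable", {
  corpus <- generate_corpus(small_config)
  paths <- parse_path_corpus(corpus$records)
  path_ids <- vapply(paths, `[[`, character(1), "indication_id")
  for (entry in corpus$registry) {
    p <- paths[[match(entry$path_id, path_ids)]]
    expect_true(entry$truth_curie %in% p$nodes$curie)
    expect_equal(p$drug_curie, entry$drug_curie)
    expect_equal(p$disease_curie, entry$disease_curie)
  }
  # gene resolver map covers every gene registry truth
  gene_entries <- Filter(function(e) e$benchmark == "gene", corpus$registry)
  for (e in gene_entries) {
    expect_equal(unname(corpus$resolver_map[e$truth_curie]), e$truth_label)
  }
})

test_that("write_corpus emits a YAML corpus the parser round-trips", {
  corpus <- generate_corpus(small_config)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  expect_true(all(file.exists(file.path(dir, c("corpus.yaml", "registry.jsonl",
                                               "resolver_map.json", "manifest.json")))))
  paths <- parse_path_corpus(file.path(dir, "corpus.yaml"))
  expect_length(paths, length(corpus$records))
})

test_that("transport coverage 1 surfaces every truth, coverage 0 none", {
  corpus <- generate_corpus(small_config)
  paths <- parse_path_corpus(corpus$records)
  items <- c(build_gene_benchmark(paths, make_static_resolver(corpus$resolver_map)),
             build_metabolite_benchmark(paths),
             build_drug_benchmark(paths))
  label_by_q <- setNames(vapply(items, `[[`, character(1), "truth_label"),
                         vapply(items, `[[`, character(1), "item_id"))
  full <- generate_transport(corpus, coverage = 1)
  none <- generate_transport(corpus, coverage = 0)
  for (it in items) {
    st_full <- retrieve_for_item(it, full)
    st_none <- retrieve_for_item(it, none)
    texts_full <- paste(vapply(st_full, `[[`, character(1), "text"), collapse = "\n")
    texts_none <- paste(vapply(st_none, `[[`, character(1), "text"), collapse = "\n")
    expect_match(texts_full, label_by_q[[it$item_id]], fixed = TRUE)
    expect_false(grepl(label_by_q[[it$item_id]], texts_none, fixed = TRUE))
    # distractors are present in every non-empty response
    expect_gt(length(st_none), 0)
  }
})

test_that("transport answers unknown pinned curies with an empty knowledge graph", {
  corpus <- generate_corpus(small_config)
  transport <- generate_transport(corpus, coverage = 1)
  resp <- transport(build_query("MONDO:9999999", "biolink:Disease", "biolink:Gene"))
  parsed <- parse_response(resp)
  expect_length(parsed$nodes, 0)
  expect_length(parsed$edges, 0)
})

test_that("transport responses are schema-valid and deterministic", {
  corpus <- generate_corpus(small_config)
  transport <- generate_transport(corpus, coverage = 0.5)
  entry <- corpus$registry[[1]]
  req <- build_query(entry$disease_curie, "biolink:Disease", "biolink:Gene")
  r1 <- transport(req)
  r2 <- transport(req)
  expect_identical(serialize_trapi(r1), serialize_trapi(r2))
  parsed <- parse_response(r1)
  for (ed in parsed$edges) {
    expect_true(ed$subject_curie %in% names(parsed$nodes))
    expect_true(ed$object_curie %in% names(parsed$nodes))
    expect_equal(ed$sources, "infores:synthetic-kg")
  }
})

test_that("the token-hash embedder normalizes, is deterministic and orthogonal on disjoint tokens", {
  emb <- make_hash_embedder(256)
  expect_identical(emb$embed("EGFR inhibitor"), emb$embed("egfr  inhibitor"))
  expect_equal(cosine(emb$embed("aspirin treats fever"),
                      emb$embed("aspirin treats fever")), 1.0, tolerance = 1e-12)
  expect_equal(cosine(emb$embed("aspirin fever"), emb$embed("gene disease")), 0.0,
               tolerance = 1e-12)
  expect_length(emb$embed("anything at all"), 256)
  expect_error(make_hash_embedder(4), ">= 8")
})

test_that("scripted backend policy: prior knowledge and context-driven answers", {
  corpus <- generate_corpus(small_config)
  paths <- parse_path_corpus(corpus$records)
  items <- build_gene_benchmark(paths, make_static_resolver(corpus$resolver_map))
  transport <- generate_transport(corpus, coverage = 1)
  key <- default_answer_keys()[["gene"]]
  cfg <- make_generation_config(key)

  # prior 0, truth-covering context -> truth returned
  b0 <- make_scripted_backend(corpus$registry, prior_knowledge = 0, seed = 7)
  it <- items[[1]]
  sts <- retrieve_for_item(it, transport)
  with_ctx <- run_item(it, b0, sts, cfg)
  expect_equal(with_ctx$answer, it$truth_label)
  # prior 0, no context -> unknown
  no_ctx <- run_item(it, b0, config = cfg)
  expect_equal(no_ctx$answer, "unknown")
  # prior 1, no context -> truth for every item
  b1 <- make_scripted_backend(corpus$registry, prior_knowledge = 1, seed = 7)
  for (item in items) {
    expect_equal(run_item(item, b1, config = cfg)$answer, item$truth_label)
  }
  # the reply is always a single structured object under the answer key
  bundle <- assemble_prompt(it, mode = "llm_only")
  raw <- b0$generate(bundle, cfg)
  expect_equal(names(jsonlite::fromJSON(raw)), key)
})

test_that("scripted backend knows exactly round(prior * n) items per benchmark", {
  corpus <- generate_corpus(small_config)
  for (q in c(0, 0.25, 0.5, 1)) {
    backend <- make_scripted_backend(corpus$registry, prior_knowledge = q, seed = 3)
    known <- attr(backend, "known_path_ids")
    for (b in c("gene", "metabolite", "drug")) {
      entries <- Filter(function(e) e$benchmark == b, corpus$registry)
      ids <- vapply(entries, `[[`, character(1), "path_id")
      expect_equal(sum(ids %in% known), round(q * length(ids)))
    }
  }
})
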