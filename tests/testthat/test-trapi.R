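# TRAPI query construction, response parsing and verbalization.

test_that("build_query emits a two-node, one-edge query graph with pinned ids", {
  q <- build_query("MONDO:0005148", "biolink:Disease", "biolink:Gene")
  qg <- q$message$query_graph
  expect_length(qg$nodes, 2)
  expect_length(qg$edges, 1)
  expect_equal(qg$nodes$n0$ids, list("MONDO:0005148"))
  expect_equal(qg$nodes$n0$categories, list("biolink:Disease"))
  expect_equal(qg$nodes$n1$categories, list("biolink:Gene"))
  expect_null(qg$nodes$n1$ids)
  expect_equal(qg$edges$e0$subject, "n0")

  # identical inputs -> identical serialized bytes
  expect_identical(serialize_trapi(build_query("MONDO:0005148", "biolink:Disease", "biolink:Gene")),
                   serialize_trapi(q))
  expect_error(build_query("", "biolink:Disease", "biolink:Gene"), "CURIE")
  expect_error(build_query("nocolon", "biolink:Disease", "biolink:Gene"), "CURIE")
})

test_that("serialize/parse round trip preserves pinned curie and categories", {
  cases <- list(
    c("MONDO:0005148", "biolink:Disease", "biolink:Gene"),
    c("CHEBI:4167", "biolink:ChemicalEntity", "biolink:Disease"),
    c("DB00945", "biolink:Drug", "biolink:BiologicalProcess"),
    c("GO:0008150", "biolink:BiologicalProcess", "biolink:ChemicalEntity")
  )
  for (cs in cases) {
    q <- build_query(cs[1], cs[2], cs[3])
    back <- parse_query(serialize_trapi(q))
    expect_equal(back$subject_curie, cs[1])
    expect_equal(back$subject_category, cs[2])
    expect_equal(back$object_category, cs[3])
  }
  q <- build_query("MONDO:1", "biolink:Disease", "biolink:Gene",
                   predicate = "biolink:condition_associated_with_gene")
  expect_equal(parse_query(serialize_trapi(q))$predicate,
               "biolink:condition_associated_with_gene")
})

test_that("parse_response captures nodes/edges and provenance", {
  parsed <- parse_response(tiny_trapi_response())
  expect_length(parsed$nodes, 2)
  expect_length(parsed$edges, 1)
  expect_equal(parsed$edges[[1]]$sources, "ctd")
  expect_equal(parsed$nodes[["NCBIGene:1"]]$name, "gene Y")

  # JSON string input parses the same
  parsed2 <- parse_response(serialize_trapi(tiny_trapi_response()))
  expect_equal(parsed2$edges, parsed$edges)

  empty <- list(message = list(knowledge_graph = list(nodes = list(), edges = list())))
  expect_equal(parse_response(empty), list(nodes = list(), edges = list()))
  expect_error(parse_response(list(message = list())), "knowledge_graph")
})

test_that("parse_response drops dangling edges with a warning, keeps nodes", {
  resp <- tiny_trapi_response()
  resp$message$knowledge_graph$edges$e1 <- list(
    subject = "MESH:D000001", predicate = "biolink:affects", object = "MISSING:1",
    sources = list())
  expect_warning(parsed <- parse_response(resp), "dropping edge")
  expect_length(parsed$edges, 1)
  expect_length(parsed$nodes, 2)
})

test_that("parse_response falls back to curie when a node name is absent", {
  resp <- tiny_trapi_response()
  resp$message$knowledge_graph$nodes[["NCBIGene:1"]]$name <- NULL
  parsed <- parse_response(resp)
  expect_equal(parsed$nodes[["NCBIGene:1"]]$name, "NCBIGene:1")
})

test_that("verbalize renders subject, humanized predicate, object and provenance", {
  parsed <- parse_response(tiny_trapi_response())
  st <- verbalize(parsed$edges, parsed$nodes, origin_query = "drug->Gene")
  expect_length(st, 1)
  expect_match(st[[1]]$text, "^drug X inhibits gene Y")
  expect_match(st[[1]]$text, "(source: ctd)", fixed = TRUE)
  expect_equal(st[[1]]$origin_query, "drug->Gene")
  expect_equal(verbalize(list(), parsed$nodes), list())
  expect_equal(bterag:::humanize_predicate("biolink:interacts_with"), "interacts with")
})

test_that("verbalize is injective on distinct tuples with distinct names", {
  nodes <- list(
    "A:1" = list(curie = "A:1", name = "alpha", categories = "x"),
    "B:1" = list(curie = "B:1", name = "beta", categories = "x"),
    "C:1" = list(curie = "C:1", name = "gamma", categories = "x")
  )
  edges <- list(
    list(subject_curie = "A:1", predicate = "biolink:affects", object_curie = "B:1", sources = "s1"),
    list(subject_curie = "A:1", predicate = "biolink:affects", object_curie = "C:1", sources = "s1"),
    list(subject_curie = "A:1", predicate = "biolink:inhibits", object_curie = "B:1", sources = "s1"),
    list(subject_curie = "A:1", predicate = "biolink:affects", object_curie = "B:1", sources = "s2")
  )
  texts <- vapply(verbalize(edges, nodes), `[[`, character(1), "text")
  expect_equal(length(unique(texts)), 4)
})

test_that("retrieve_for_item runs the plan, de-duplicates triples and unions sources", {
  item <- tiny_item()
  # transport answers every slot with the same truth triple, varying source
  calls <- new.env(); calls$n <- 0L
  transport <- function(req) {
    calls$n <- calls$n + 1L
    resp <- tiny_trapi_response()
    resp$message$knowledge_graph$edges$e0$sources <-
      list(list(resource_id = paste0("src", calls$n),
                resource_role = "primary_knowledge_source"))
    resp
  }
  st <- retrieve_for_item(item, transport)
  expect_equal(calls$n, 4)  # gene plan: disease/drug x Gene/Protein
  expect_length(st, 1)      # duplicate triple appears once
  expect_setequal(st[[1]]$sources, paste0("src", 1:4))
  expect_match(st[[1]]$text, "^drug X inhibits gene Y \\(source: ")
  keys <- vapply(st, function(s) paste(s$subject_curie, s$predicate, s$object_curie),
                 character(1))
  expect_false(any(duplicated(keys)))
})

test_that("retrieve_for_item tolerates partial failures but not total failure", {
  item <- tiny_item()
  n <- new.env(); n$i <- 0L
  flaky <- function(req) {
    n$i <- n$i + 1L
    if (n$i == 1L) stop("boom")
    list(message = list(knowledge_graph = list(nodes = list(), edges = list())))
  }
  expect_warning(st <- retrieve_for_item(item, flaky), "failed")
  expect_equal(st, list())
  dead <- function(req) stop("down")
  expect_error(suppressWarnings(retrieve_for_item(item, dead)), "all retrieval slots failed")
})

test_that("metabolite and drug plans pin the documented anchors", {
  seen <- list()
  spy <- function(req) {
    seen[[length(seen) + 1L]] <<- parse_query(req)
    list(message = list(knowledge_graph = list(nodes = list(), edges = list())))
  }
  met <- tiny_item(benchmark = "metabolite")
  invisible(retrieve_for_item(met, spy))
  expect_equal(vapply(seen, `[[`, character(1), "subject_curie"),
               c(met$disease_curie, met$drug_curie))
  expect_true(all(vapply(seen, `[[`, character(1), "object_category") ==
                    "biolink:ChemicalEntity"))
  seen <- list()
  drug <- tiny_item(benchmark = "drug", anchor_curie = "GO:0001")
  invisible(retrieve_for_item(drug, spy))
  expect_equal(vapply(seen, `[[`, character(1), "subject_curie"),
               c(drug$disease_curie, "GO:0001"))
})

test_that("the retrieval cache replays responses without re-calling the transport", {
  item <- tiny_item()
  cache <- withr::local_tempdir()
  calls <- new.env(); calls$n <- 0L
  transport <- function(req) {
    calls$n <- calls$n + 1L
    tiny_trapi_response()
  }
  st1 <- retrieve_for_item(item, transport, cache_dir = cache)
  first <- calls$n
  st2 <- retrieve_for_item(item, transport, cache_dir = cache)
  expect_equal(calls$n, first)  # all slots served from cache
  expect_equal(st1, st2)
})
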