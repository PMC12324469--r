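Package: bterag
Title: Knowledge-Graph Retrieval-Augmented Generation for Mechanistic Biomedical QA
Version: 0.1.0
Authors@R:
    person("BTE-RAG", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Builds mechanistic question-answering benchmarks from curated
    drug-to-disease mechanism-of-action paths (gene-, metabolite- and
    drug-centric), retrieves supporting evidence from Translator Reasoner API
    (TRAPI) knowledge-graph services, verbalizes returned triples into
    provenance-annotated context statements, prunes context by embedding
    cosine-similarity percentiles, runs dual-path inference (LLM-only versus
    retrieval-augmented) through a pluggable deterministic generation backend,
    and evaluates answers with exact-match and semantic-concordance analytics
    (accuracy, flip cross-tabulations, rank-ordered similarity curves and
    histograms). Ships a seeded synthetic-fixture generator (corpora, TRAPI
    transports, a token-hash embedder and scripted backends) so the entire
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
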