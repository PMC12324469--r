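---
title: "Methods: benchmark construction, knowledge-graph RAG and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark construction, knowledge-graph RAG and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bterag)
```

## The problem and the design

Mechanism-of-action knowledge — which gene a drug acts through, which
metabolite it perturbs, which drug targets a given biological process in a
disease — is curated in knowledge graphs as typed paths from a drug node,
through intermediate entities (genes, proteins, metabolites, biological
processes), to a disease node. A language model asked such a question may
answer from parametric memory, correctly or not. The experiment this package
operationalizes compares two inference routes over identical questions:

* **LLM-only** — the question alone;
* **RAG** — the question preceded by declarative context statements
  verbalized from one-hop TRAPI knowledge-graph retrievals.

Both routes run deterministically (temperature 0) through the same backend,
so any difference in correctness is attributable to the retrieved context.
The 2×2 flip table (both correct / flipped to correct / flipped to
incorrect / both incorrect) is the primary read-out of that difference.

## Benchmark construction rules

Mechanism records are parsed from the `graph`/`nodes`/`links` dialect
(YAML or JSON); the ordered node list must start at the drug and end at the
disease. Three benchmarks are built by conjunctive structural filters:

* **gene** — internal nodes (endpoints excluded) contain *exactly one*
  `biolink:Gene` node. `biolink:Protein` nodes do **not** qualify: the
  benchmark targets the gene entity proper, and counting proteins would
  silently merge two distinct curation conventions; retrieval, by contrast,
  queries both Gene and Protein categories, because evidence about either
  supports the same answer. The gene identifier must resolve to an HGNC
  symbol; the resolver is injectable and its sentinels (`ambiguous`,
  `deprecated`, `not_found`) all exclude the path, mirroring the removal of
  deprecated or ambiguous identifiers.
* **metabolite** — paths consisting exclusively of taxonomic predicates
  (default set `{biolink:subclass_of, subclass}`, matched case-insensitively
  with the `biolink:` prefix ignored) are dropped first: a chain of "is-a"
  links carries no mechanism. Then exactly one internal `CHEBI:`-prefixed
  node is required (prefix matching is case-insensitive, local ids verbatim),
  and any drug–disease indication represented by more than one qualifying
  path is excluded outright — with several candidate mechanisms the single
  ground-truth answer would be ill-posed.
* **drug** — exactly one `biolink:BiologicalProcess` node anywhere in the
  path, and the drug identifier must be in the DrugBank or MeSH namespace
  (bare `DB\d+` accessions are accepted as DrugBank identifiers because
  public mechanism corpora serialize them without a prefix). The question is
  anchored on the disease and the process; the drug is the answer.

Deduplication across indications keys on the normalized question text
(lower-cased, whitespace-collapsed) plus the upper-cased truth label; merged
items union their source path ids, and the stable item id is a short hash of
that key so items join reproducibly across runs. The exact key the original
benchmark used is not documented; this one is the natural reading of
"deduplication across indications" (same wording, same answer) and is the
package's own choice.

## Retrieval and verbalization

Each benchmark has a fixed query plan of one-hop TRAPI queries — gene:
{disease→Gene, disease→Protein, drug→Gene, drug→Protein}; metabolite:
{disease→ChemicalEntity, drug→ChemicalEntity}; drug: {disease→ChemicalEntity,
process→ChemicalEntity}. `biolink:ChemicalEntity` is the configurable default
for "biochemical/chemical entities"; no predicate constraint is applied by
default. Issuing Gene and Protein as separate slots (rather than one
multi-category node) keeps every returned edge attributable to its slot.

Edges are rendered subject → predicate → object exactly as returned (no
re-orientation of passive predicates), with the `biolink:` prefix stripped
and underscores spaced, plus a provenance suffix listing the primary
knowledge sources. Duplicate triples across slots keep the first occurrence
and union their sources. Responses can be cached on disk keyed by a hash of
the canonical request serialization, making runs offline-replayable.

## Context selection

Question and statement texts are embedded and scored by cosine similarity.
Pruning at percentile `p` drops the `k = floor(p·n/100)` lowest-scored
statements, ties broken in favour of earlier statements. The count rule was
chosen over interpolated percentile *values* because it is unambiguous with
ties and small `n`, reproduces "remove the lowest 10%" exactly, and renders
the retain/prune phrasings equivalent; it also sidesteps the question of
whether a threshold at the boundary value is strict or inclusive. Scores are
computed on the statement text without the provenance suffix (configurable):
source tokens are metadata, not content, and would distort similarity.
Production configurations name sentence-transformer models
(`pritamdeka/S-PubMedBert-MS-MARCO` for selection,
`pritamdeka/BioBERT-mnli-snli-scinli-scitail-mednli-stsb` for evaluation);
tests use the token-hash embedder described below through the identical
contract.

## Inference and parsing

System prompts are shipped as editable, versioned template files (the
original wording is not public; these templates state the same contract: a
single JSON object under the benchmark's answer key — `gene`,
`biochemical_entity`, `drug` — with no surrounding text). Zero-shot only; no
few-shot examples, no chain-of-thought. Answer parsing strips optional code
fences, isolates the first balanced JSON object, and requires a scalar
string at the answer key; anything else is a recorded parse failure scored
as incorrect rather than an aborted run — excluding failures would inflate
accuracy.

## Evaluation

Exact matching is case-insensitive on trimmed strings (suitable for HGNC
symbols). Semantic concordance is the cosine of the two answers' embeddings;
empty or unparseable predictions score the sentinel −1. Classification as
accurate uses an inclusive `score ≥ threshold` everywhere, consistent with
the high-fidelity zone convention (cosine ≥ 0.90); 0.90 is the default
semantic threshold and is a package choice, not a documented value.
Histograms tile `[0, 1]` with half-open bins (default width 0.05, the
figures' granularity), the top bin right-closed so 1.0 is counted, and an
underflow bin pooling sentinel scores, so counts always sum to `n`.

## The synthetic world

`generate_corpus(corpus_config(...))` states one fixed world per seed:
gene paths (exactly one internal Gene node, half with an extra Protein
intermediate), metabolite paths (one CHEBI node, non-taxonomic predicates,
unique indication), process paths (one BiologicalProcess, alternating
DrugBank/MeSH drug namespaces), decoys each violating exactly one filter
(protein-only intermediate; all-taxonomic path; duplicated indication;
`UNII:` drug namespace; two process nodes) and two-gene paths. Every record
gets a unique drug–disease pair, so the registry of eligible paths *is* the
expected benchmark, item for item — the central oracle for the builders. The
default configuration (60/60/50/20/10 paths, 3 distractor edges per query,
seed 42) was chosen once as a realistic desk-scale corpus exercising every
filter; it is not tuned to any test outcome.

The fixture transport serves, for exactly `round(coverage · n)` eligible
items per benchmark (a seeded draw), the edge linking a query anchor to the
truth entity, plus deterministic distractor edges whose names cannot collide
with truth labels. The scripted backend answers the truth for exactly
`round(prior_knowledge · n)` items per benchmark without context, `"unknown"`
otherwise; with context it answers any ground-truth entity whose name
co-occurs (word-boundary string containment) with one of the item's anchor
names on a context line. The coverage and prior-knowledge draws use
different seeds so the covered and known sets are independent samples.

This construction makes accuracies exact arithmetic: LLM-only accuracy
equals the prior fraction; RAG accuracy equals the fraction of items either
covered or known; zero coverage reduces RAG to the baseline exactly. A green
end-to-end test therefore establishes that retrieval, pruning, prompt
assembly, parsing and scoring compose without loss — it does **not**
establish anything about real corpora, real knowledge-graph noise, real
embedding geometry or real model behaviour, and the synthetic vocabulary has
none of the lexical ambiguity of actual biomedical names.

## Numerical and degenerate-input choices

* Cosine of a zero vector is an error, not 0: a zero embedding signals a
  broken embedder, except for the deliberate empty-text/empty-answer
  sentinel (−1), which is handled before embedding.
* `filter_by_percentile` at `p = 100` drops everything; `n = 0` returns
  empty; survivor order is input order.
* Item processing is benchmark-file order; no parallelism is promised, and
  the request-hash cache would keep outputs identical under a concurrent
  adapter.
* All randomness flows through per-artifact seeds via scoped RNG state; no
  global seed is touched.

## Known limitations

* No live TRAPI or chat-completion adapter is shipped (the transport and
  backend contracts, with retry policy left to live adapters, are the
  integration points); fixtures stand in for both.
* One-hop query graphs only; no TRAPI result-score ranking.
* The entity-extraction operation exists for free-text use but benchmark
  runs bypass it, as items carry pre-annotated identifiers.
* Semantic evaluation with the token-hash embedder is a structural stand-in;
  its similarity values are not comparable to transformer embeddings.
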