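---
title: "Ranked retrieval of annotated SBML models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked retrieval of annotated SBML models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrank)
```

## The retrieval model

An annotated bio-model is a pair of machine-readable source (here: SBML
Level 2) and annotation information — MIRIAM URN triplets of data type,
identifier and qualifier attached to the model or its elements. mrank
maps every model onto a feature-classified representation: a set of
(feature, term-multiset) pairs plus (feature, URI/qualifier) pairs. The
feature schema groups 26 features into six dimensions:

| dimension | features | importance |
|---|---|---|
| constituents | modelName, species, compartment, reaction, parameter, event, function, modelDescription + the seven `*URI` twins | very high |
| persons | author, encoder, submitter | medium |
| publication | publicationURI, publicationText | high |
| user content | content | very high |
| dates | creationDate, modificationDate | low |
| administrative | id, additionalId, path | low |

Each feature carries a numeric weight (`inst/extdata/feature_weights.yaml`);
URI features dominate (5 for model/species/compartment/reaction URIs)
because an annotation link identifies a constituent far more reliably
than its free-text name. Each qualifier carries a weight too
(`inst/extdata/qualifier_weights.yaml`): `is` (2.0) asserts identity and
outweighs composition/version relations (1.5), encoding relations (1.3)
and descriptive ones (1.0). Both matrices are plain YAML and can be
swapped per engine.

Two query modes exist. *Query by value* (QBV) is fielded free text:
`+species@is:(caffeine) compartment:(gut) -author:(john doe)
date:([01/01/2009 - *])`. *Query by model example* (QBME) featurizes an
entire model and turns every non-empty term or URI feature into a SHOULD
clause; enrichment is switched off because the example already provides
its own context. Date features are not queried in QBME — only terms and
URIs are compared verbatim.

## Semantic index

The semantic index holds one entry per URI occurring in the corpus:
links per vocabulary-prefixed qualifier (`bqbiol_is`, `bqmodel_is`, ...)
to the models carrying it, plus descriptive content resolved from an
offline lexicon (names, synonyms, formulas, cross-reference keywords).
Resolution of keywords to URIs treats each entry's content as a document
and scores

\[ w(q, e) = \cos\big(v(q), v(e)\big), \qquad
   v_t = \sqrt{tf_t}\,\Big(1 + \ln\frac{N}{1+df_t}\Big) \]

with document frequencies over semantic entries. The weight is a plain
cosine in (0, 1]; no max-normalization or scorer-specific boosting is
applied, so the weights are comparable across queries but are not meant
to reproduce any particular production system's boost values. A
qualifier filter keeps only entries linked through one of the named
qualifiers, matched vocabulary-agnostically (`is` accepts `bqbiol_is`
and `bqmodel_is`). Ties break by ascending URI for determinism; the
default `k = 10` resolved URIs per clause keeps weakly related entries
available to the ranker without flooding the query.

## Ontology expansion

Queries for a constituent should also reach models encoding structurally
related constituents. mrank expands query terms through OBO 1.2
ontologies by breadth-first search: a term matches nodes by name or
synonym (case-insensitive), and every node within undirected distance
`radius` contributes its name and synonyms with weight
`decay^distance`. Defaults are `radius = 2`, `decay = 0.5`: one hop
halves the boost, so an exact hit always dominates an expanded one, and
the seed itself (distance 0) keeps weight 1. Edge labels (`is_a`,
`part_of`) are treated equally for distance; a labeled-edge weighting
hook would be the natural refinement but uniform treatment keeps the
expansion symmetric and predictable. Multi-word names and synonyms are
tokenized and each token inherits the decayed boost, since the scorer
operates on single tokens. Expansion terms always enter the assembled
query as SHOULD clauses regardless of the parent clause's occurrence:
expansions are suggestions, not requirements.

## Query assembly

Parsing yields sub-queries with pairwise-disjoint features. Assembly
then, for each constituent term clause with enrichment on:

* resolves the terms against the semantic index (honoring the
  qualifier restriction) and emits a sibling URI clause on the
  corresponding URI feature (`species` → `speciesURI`) with the resolved
  weights as boosts;
* expands the terms through each ontology into a SHOULD clause on the
  same feature;
* always retains the original literal clause, so models that spell the
  constituent in plain text still match even without annotations.

A MUST parent makes its derived URI clause MUST *in the same group*: the
pair is satisfied when either member matches. This is what lets a query
demand that a species "must be exactly caffeine" and still retrieve
models that only carry the caffeine URI, not the word. Every assembled
clause is labeled `user`, `semantic` or `ontology`; the user-labeled
subset reconstructs the parsed query exactly.

## Candidate selection and ranking

Selection is extended-boolean: a clause matches a model when at least
one of its terms or URIs occurs in the clause's feature field (dates:
within range; trailing-`*` terms: prefix match). Candidates are the
intersection of MUST-group match sets minus the union of MUST_NOT match
sets; with no MUST clause, the union of SHOULD matches minus MUST_NOT.
A query with neither MUST nor SHOULD clauses is rejected as
unsatisfiable.

Ranking sums per-clause similarities over all non-MUST_NOT clauses:

\[ score(c) = \sum_s W(f_s)\, B_s\, sim_s(c) \]

* term clause: \( sim_s(c) = \frac{\sum_{t \in s} b_t\,
  \sqrt{tf_{t,c}}\,idf_t}{\lVert c_f \rVert} \) — the boost-weighted
  tf-idf sum over the clause's terms, divided by the Euclidean norm of
  the model's field vector, so verbose fields are not rewarded;
* URI clause: \( sim_s(c) = \sum_{u \in s} b_u\, Q(\text{best qualifier
  linking } u \text{ in } c) \) — deliberately *not* field-normalized: a
  model that annotates many species must not be penalized for an exact
  URI hit; qualifier semantics, not verbosity, drive URI relevance;
* date clause: 1 when the model's date falls in range — a matching date
  only nudges a score, given the low date feature weight.

Matching more optional clauses strictly increases the score. The scorer
is intentionally simple and fully auditable: `explain()` reports each
clause's contribution, and the contributions sum to the score within
1e-9 relative tolerance. Ties in the final ordering break by ascending
model id. Alternative similarity functions can be explored by editing
the weight matrices or by scoring candidates with a custom function over
the exposed index statistics (`term_weight()` and the serialized
postings).

## Numerical choices and degenerate inputs

* `idf = 1 + ln(N/(1+df))` stays strictly positive for any `df ≤ N`
  (worst case `1 + ln(N/(N+1)) > 0.3`), so scores are never negative.
* Cosine weights are clamped to 1 to absorb floating-point overshoot.
* Empty fields have norm 0 and contribute 0 (no division by zero);
  empty models featurize to empty-but-valid representations; an empty
  corpus builds an empty index with `doc_count` 0.
* URN normalization lowercases the namespace, percent-decodes the
  identifier (preserving its case) and re-encodes `":"` as `"%3A"`; the
  operation is idempotent. Unknown qualifiers and malformed URNs are
  skipped with warnings rather than failing a parse.
* SBO term attributes are indexed as annotations with namespace
  `biomodels.sbo` and qualifier `is`; the two qualifier vocabularies are
  stored distinctly but share one weight per qualifier name.
* The `date` query feature aliases `creationDate` (submission date);
  `modificationDate` is addressable explicitly. Dates parse from ISO
  8601 or `dd/MM/yyyy`.
* Free-text queries without any clause syntax search all term features
  as SHOULD clauses; stray text next to clause syntax is a parse error
  with a position, rather than being guessed at.

## The synthetic corpus generator

`gen_corpus()` emulates a small curated repository: models with 1–4
species, 1–2 compartments and 0–3 reactions drawn from a built-in
vocabulary of real compounds, cell components and processes with their
ChEBI/GO/KEGG URNs; creators, creation/modification dates (2005–2010)
and note text drawn from fixed pools; a fraction `annotation_density`
(default 0.8, the typical situation of a mostly but not fully annotated
corpus) of elements annotated under qualifiers drawn from a mix
dominated by `is` (0.5) with `isVersionOf`, `hasPart`, `hasVersion`,
`isHomologTo` sharing the rest — identity links dominate curated
annotation practice. All randomness is threaded through one explicit
seed and the caller's RNG state is restored, so identical arguments give
byte-identical SBML.

What the generator does *not* emulate: multi-thousand-term notes,
nested/composite annotations, CellML or BioPAX sources, inconsistent
hand-written RDF, and corpus-scale statistics of real repositories.
Passing tests on generated corpora therefore demonstrate correctness of
the indexing/scoring pipeline, not retrieval quality on a real
repository.

The packaged worked example is built by `worked_example_fixture()`:
three models around caffeine in the digestive tract, a four-entry
lexicon of ChEBI/KEGG keyword streams, and a mini-ontology
(caffeine → methylxanthine → xanthine) — small enough that every number
it produces can be checked by hand. The third model deliberately links
the xanthine and glyoxylate URIs only via `isVersionOf`, so it is
retrieved purely through a weakly-qualified annotation and must rank
last; the glyoxylate URI also demonstrates the qualifier filter, which
removes it from `is`-restricted resolution.

## Verification

The test suite checks each module against hand-evaluated or brute-force
oracles: field norms and ranking scores are compared with an independent
scorer that recomputes tf, idf, norms and clause sums directly from raw
representations (100 seeded corpora of 3–10 models with random ≤5-clause
queries, 1e-9 relative tolerance — sizes chosen so the whole suite runs
in well under a minute), semantic resolution against a hand-rolled
cosine, ontology expansion against the closed form `decay^distance`.
Property tests cover MUST_NOT exclusion completeness, qualifier and idf
monotonicity, expansion radius monotonicity and symmetry, enrichment
monotonicity of candidate sets, QBME self-retrieval at rank 1, and
byte-determinism of the generator. `scripts/acceptance.R` re-runs the
worked example and the oracle comparison from scratch and writes the
measured values to JSON.

## Known limitations

* Only SBML Level 2-style documents are read; CellML/BioPAX are out of
  scope, as are model mathematics and simulatability.
* The lexicon is offline by design; URIs absent from it get empty
  content and cannot be reached by keyword (they remain reachable by
  URI and through qualifier links).
* No phrase, fuzzy or proximity operators — only wildcard prefixes and
  date ranges beyond plain terms.
* The index is rebuilt offline; there are no incremental updates.
* Encoder/submitter roles are schema-supported but SBML RDF only
  distinguishes creators, so in practice only `author` is populated.
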