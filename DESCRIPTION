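Package: mrank
Title: Ranked Retrieval of Annotated Systems Biology Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Search engine for collections of SBML models carrying MIRIAM
    annotation URNs. Models are split into weighted features (constituents,
    persons, dates, publication, user content, administrative data) and
    indexed per feature; a semantic index maps keywords to qualifier-typed
    annotation URIs via tf-idf cosine scoring; OBO ontologies expand queries
    with distance-decayed related terms; candidates are selected with
    extended-boolean MUST/SHOULD/MUST_NOT clause algebra and ranked with a
    weighted vector-space scorer. Supports query-by-value (fielded free
    text) and query-by-model-example, with per-clause score explanations
    and a deterministic synthetic-corpus generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
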