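test_that("the example query parses into four clauses with the right occurrences", {
  q <- parse_query(paste("+species@is:(caffeine) compartment:(gut)",
                         "-author:(john doe) date:([01/01/2009 - *])"))
  expect_length(q$clauses, 4L)
  occ <- vapply(q$clauses, `[[`, "", "occurrence")
  expect_identical(occ, c("MUST", "SHOULD", "MUST_NOT", "SHOULD"))
  expect_identical(q$clauses[[1]]$qualifiers, "is")
  expect_identical(q$clauses[[3]]$terms$term, c("john", "doe"))
  expect_identical(q$clauses[[4]]$feature, "creationDate")
  expect_identical(q$clauses[[4]]$date_range[1], as.Date("2009-01-01"))
  expect_true(is.na(q$clauses[[4]]$date_range[2]))
})

test_that("term boosts, wildcards and parse errors behave per the grammar", {
  q <- parse_query("species:(caffeine^2)")
  expect_identical(q$clauses[[1]]$occurrence, "SHOULD")
  expect_identical(q$clauses[[1]]$terms$boost, 2)
  expect_identical(parse_query("species:(caf*)")$clauses[[1]]$terms$term, "caf*")
  expect_error(parse_query("species:(caffeine) species:(xanthine)"),
               "disjoint")
  expect_error(parse_query("speciez:(caffeine)"), "unknown feature")
  expect_error(parse_query("species:(caffeine^x)"), "malformed boost")
  expect_error(parse_query("date:([yesterday - *])"), "unparseable date")
  expect_error(parse_query("species:(caffeine) stray"), "unexpected text")
})

test_that("free text with no feature prefix becomes SHOULD clauses over all term features", {
  q <- parse_query("calcium oscillations")
  schema <- default_feature_schema()
  expect_identical(vapply(q$clauses, `[[`, "", "feature"),
                   schema$feature[schema$kind == "term"])
  expect_true(all(vapply(q$clauses, `[[`, "", "occurrence") == "SHOULD"))
  expect_true(all(vapply(q$clauses, function(cl)
    identical(cl$terms$term, c("calcium", "oscillations")), logical(1))))
})

test_that("assembly resolves constituents to URI clauses and keeps the originals", {
  eng <- worked_example_engine()
  q <- parse_query("+species@is:(caffeine)")
  aq <- assemble(q, sem = eng$semantic, onts = eng$ontologies, k = 10)
  prov <- vapply(aq$clauses, `[[`, "", "provenance")
  expect_identical(prov, c("user", "semantic", "ontology"))
  # user clause retained verbatim
  expect_identical(aq$clauses[[1]]$terms$term, "caffeine")
  # MUST propagates to the derived URI clause within one group
  expect_identical(aq$clauses[[2]]$occurrence, "MUST")
  expect_identical(aq$clauses[[2]]$group, aq$clauses[[1]]$group)
  expect_identical(aq$clauses[[2]]$feature, "speciesURI")
  expect_setequal(aq$clauses[[2]]$uris$uri,
                  c("urn:miriam:obo.chebi:CHEBI%3A27732",
                    "urn:miriam:kegg.compound:C07481",
                    "urn:miriam:kegg.compound:C00385"))
  expect_true(all(diff(aq$clauses[[2]]$uris$boost) <= 0))
  # ontology-derived terms are SHOULD with decayed boosts
  expect_identical(aq$clauses[[3]]$occurrence, "SHOULD")
  xan <- aq$clauses[[3]]$terms
  expect_equal(xan$boost[xan$term == "xanthine"], 0.25, tolerance = 1e-12)
})

test_that("assembly with enrichment off is the identity on clause structure", {
  eng <- worked_example_engine()
  q <- parse_query("species:(caffeine) compartment:(gut)")
  q$clauses <- lapply(q$clauses, function(cl) { cl$enrich <- FALSE; cl })
  aq <- assemble(q, sem = eng$semantic, onts = eng$ontologies)
  expect_length(aq$clauses, 2L)
  expect_true(all(vapply(aq$clauses, `[[`, "", "provenance") == "user"))
})

test_that("provenance labels reconstruct the user query exactly", {
  eng <- worked_example_engine()
  fx <- worked_example_fixture()
  q <- parse_query(fx$query)
  aq <- assemble(q, sem = eng$semantic, onts = eng$ontologies)
  user <- aq$clauses[vapply(aq$clauses, `[[`, "", "provenance") == "user"]
  expect_length(user, length(q$clauses))
  for (i in seq_along(user)) {
    expect_identical(user[[i]]$feature, q$clauses[[i]]$feature)
    expect_identical(user[[i]]$occurrence, q$clauses[[i]]$occurrence)
    if (!is.null(q$clauses[[i]]$terms))
      expect_identical(user[[i]]$terms, q$clauses[[i]]$terms)
  }
  expect_true(all(vapply(aq$clauses, `[[`, "", "provenance") %in%
                  c("user", "semantic", "ontology")))
})

test_that("the worked-example query returns the three models in the expected order", {
  eng <- worked_example_engine()
  fx <- worked_example_fixture()
  res <- search_qbv(eng, fx$query)
  expect_identical(res$model_id,
                   c("BIOMD0000000241", "BIOMD0000000015", "BIOMD0000000220"))
  expect_true(all(diff(res$score) < 0))
  # nothing matches an unknown constituent
  expect_identical(nrow(search_qbv(eng, "+species:(zyzzyva)")), 0L)
})

test_that("enrichment never shrinks the candidate set of SHOULD-only queries", {
  eng <- worked_example_engine()
  for (expr in c("species:(caffeine)", "species:(xanthine)",
                 "compartment:(gut) species:(caffeine)")) {
    with_e <- search_qbv(eng, expr, enrich = TRUE, k = 10)
    without <- search_qbv(eng, expr, enrich = FALSE)
    expect_true(all(without$model_id %in% with_e$model_id))
  }
})

test_that("QBME retrieves the example itself at rank 1", {
  docs <- gen_corpus(8, seed = 41)
  eng <- build_engine(lapply(names(docs), function(id)
    parse_model(docs[[id]], id)), lexicon = builtin_lexicon())
  for (id in names(docs)) {
    res <- search_qbme(eng, parse_model(docs[[id]], id))
    expect_identical(res$model_id[1], id)
  }
})

test_that("QBME ranks a near-duplicate above an unrelated model", {
  fx <- worked_example_fixture()
  a <- parse_model(fx$sbml[["BIOMD0000000241"]], "BIOMD0000000241")
  near <- a
  near$model_id <- "NEARDUP"
  kinds <- vapply(near$elements, `[[`, "", "element_kind")
  near$elements[[which(kinds == "species")[2]]]$element_name <- "theobromine"
  unrelated <- parse_model(fx$sbml[["BIOMD0000000220"]], "UNREL")
  eng <- build_engine(list(near, unrelated), lexicon = fx$lexicon)
  res <- search_qbme(eng, a)
  expect_identical(res$model_id[1], "NEARDUP")
  if ("UNREL" %in% res$model_id)
    expect_gt(res$score[res$model_id == "NEARDUP"],
              res$score[res$model_id == "UNREL"])
  # two content-identical indexed copies share the top score exactly
  c1 <- a; c1$model_id <- "C1"
  c2 <- a; c2$model_id <- "C2"
  probe <- a; probe$model_id <- "EX"   # its id matches neither copy
  eng2 <- build_engine(list(c1, c2, unrelated), lexicon = fx$lexicon)
  res2 <- search_qbme(eng2, probe)
  expect_identical(res2$model_id[1:2], c("C1", "C2"))
  expect_equal(res2$score[1], res2$score[2], tolerance = 1e-12)
})
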