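test_that("tokenization is lowercase, splits on non-alphanumerics, keeps short tokens", {
  expect_identical(tokenize("1,3,7-Trimethylxanthine (Caffeine)"),
                   c("1", "3", "7", "trimethylxanthine", "caffeine"))
  expect_identical(tokenize("c8h10n4o2"), "c8h10n4o2")
  expect_identical(tokenize(c("", NA)), character())
  # deterministic across runs
  expect_identical(tokenize("Ca2+ signalling"), tokenize("Ca2+ signalling"))
})

test_that("URN normalization decodes identifiers, lowercases namespaces, and is idempotent", {
  u <- normalize_urn("urn:miriam:obo.chebi:CHEBI%3A18021")
  expect_true(u$valid)
  expect_identical(u$data_type, "obo.chebi")
  expect_identical(u$identifier, "CHEBI:18021")
  expect_identical(u$uri, "urn:miriam:obo.chebi:CHEBI%3A18021")
  # mixed case namespace + decoded identifier input
  v <- normalize_urn("urn:miriam:OBO.GO:GO:0004396")
  expect_identical(v$uri, "urn:miriam:obo.go:GO%3A0004396")
  expect_identical(normalize_urn(v$uri)$uri, v$uri)
  expect_false(normalize_urn("http://identifiers.org/chebi/18021")$valid)
})

test_that("parse_model extracts elements, annotations, notes and name", {
  m <- parse_model(pep_sbml())
  expect_s3_class(m, "annotated_model")
  expect_identical(m$model_id, "mPEP")
  expect_identical(m$name, "glycolysis fragment")
  kinds <- vapply(m$elements, `[[`, "", "element_kind")
  expect_identical(sort(kinds), c("compartment", "species"))
  sp <- m$elements[[which(kinds == "species")]]
  expect_identical(sp$element_id, "PEP")
  expect_identical(sp$annotations$data_type, "obo.chebi")
  expect_identical(sp$annotations$identifier, "CHEBI:18021")
  expect_identical(sp$annotations$qualifier, "is")
})

test_that("parse_model handles empty listOfSpecies and rejects malformed input", {
  empty <- '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4"><model id="m1"><listOfSpecies/></model></sbml>'
  m <- parse_model(empty)
  expect_length(m$elements, 0L)
  expect_error(parse_model("<sbml><model"), "cannot parse")
  expect_error(parse_model('<foo xmlns="urn:x"><bar/></foo>'), "SBML")
  expect_error(
    parse_model('<sbml xmlns="http://www.sbml.org/sbml/level2/version4"/>'),
    "no SBML model")
})

test_that("unknown qualifiers are skipped with a warning, not fatal", {
  doc <- sub("bqbiol:is>", "bqbiol:references>", pep_sbml(), fixed = TRUE)
  doc <- sub("</bqbiol:is>", "</bqbiol:references>", doc, fixed = TRUE)
  expect_warning(m <- parse_model(doc), "unknown qualifier")
  expect_identical(nrow(extract_annotations(m)), 0L)
})

test_that("extract_annotations flattens and normalizes, keeping duplicates", {
  reaction_doc <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="rx1"><listOfReactions>',
    '<reaction id="r1"><annotation>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
    'xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
    '<rdf:Description rdf:about="#r1"><bqbiol:isVersionOf><rdf:Bag>',
    '<rdf:li rdf:resource="urn:miriam:obo.go:GO%3A0004396"/>',
    '<rdf:li rdf:resource="urn:miriam:obo.go:GO%3A0004396"/>',
    '</rdf:Bag></bqbiol:isVersionOf></rdf:Description></rdf:RDF>',
    '</annotation></reaction>',
    '</listOfReactions></model></sbml>')
  ann <- extract_annotations(parse_model(reaction_doc))
  expect_identical(nrow(ann), 2L)  # duplicates retained
  expect_identical(unique(ann$element_kind), "reaction")
  expect_identical(unique(ann$identifier), "GO:0004396")
  expect_identical(unique(ann$qualifier), "isVersionOf")
  # element with no RDF contributes nothing
  expect_identical(nrow(extract_annotations(parse_model(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4"><model id="m"><listOfSpecies><species id="s1"/></listOfSpecies></model></sbml>'))),
    0L)
})

test_that("featurize maps elements to features with id fallback for unnamed elements", {
  doc <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mgut" name="caffeine absorption">',
    '<listOfCompartments><compartment id="c1" name="gut"/></listOfCompartments>',
    '<listOfSpecies><species id="s1" name="caffeine" compartment="c1"/>',
    '<species id="re1" compartment="c1"/></listOfSpecies>',
    '</model></sbml>')
  rep <- featurize(parse_model(doc))
  expect_identical(sort(rep$assignments$species), c("caffeine", "re1"))
  expect_identical(rep$assignments$compartment, "gut")
  expect_identical(rep$assignments$modelName, c("caffeine", "absorption"))
  expect_length(rep$uri_assignments, 0L)
})

test_that("lossless coverage: every named element appears in its feature; URI counts match", {
  reps <- corpus_reps(6, seed = 11)
  docs <- gen_corpus(6, seed = 11)
  for (i in seq_along(reps)) {
    m <- parse_model(docs[[i]], names(docs)[i])
    rep <- reps[[i]]
    for (el in m$elements) {
      toks <- tokenize(el$element_name)
      if (!length(toks)) toks <- tokenize(el$element_id)
      expect_true(all(toks %in% rep$assignments[[el$element_kind]]))
    }
    ann <- extract_annotations(m)
    for (kind in c("species", "compartment", "reaction")) {
      n_ann <- sum(ann$element_kind == kind)
      ua <- rep$uri_assignments[[paste0(kind, "URI")]]
      expect_identical(if (is.null(ua)) 0L else nrow(ua), n_ann)
    }
  }
})

test_that("featurize is deterministic for identical input bytes", {
  doc <- gen_corpus(1, seed = 5)[[1]]
  expect_identical(featurize(parse_model(doc, "m")),
                   featurize(parse_model(doc, "m")))
})

test_that("model-level metadata lands in persons, dates and publication features", {
  fx <- worked_example_fixture()
  m <- parse_model(fx$sbml[["BIOMD0000000241"]], "BIOMD0000000241")
  expect_identical(m$persons$name, "Lena Vogel")
  expect_identical(m$creation_date, as.Date("2009-06-15"))
  rep <- featurize(m)
  expect_identical(sort(rep$assignments$author), c("lena", "vogel"))
  expect_identical(rep$dates$creationDate, as.Date("2009-06-15"))
  expect_identical(rep$uri_assignments$publicationURI$uri,
                   "urn:miriam:pubmed:19696443")
})
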