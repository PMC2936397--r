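# Hand-built model representations (bypassing SBML) for index/scorer tests.
make_rep <- function(model_id, assignments = list(), uri_assignments = list(),
                     dates = list()) {
  uri_assignments <- lapply(uri_assignments, function(x) {
    if (is.character(x))
      x <- data.frame(uri = x, qualifier = "is", prefix = "bqbiol",
                      stringsAsFactors = FALSE)
    if (is.null(x$prefix)) x$prefix <- "bqbiol"
    x
  })
  structure(list(model_id = model_id, assignments = assignments,
                 uri_assignments = uri_assignments, dates = dates),
            class = "model_representation")
}

# minimal SBML document with one annotated species (PEP / ChEBI:18021)
pep_sbml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '<model id="mPEP" name="glycolysis fragment">\n',
    '<listOfCompartments><compartment id="cyt" name="cytosol"/></listOfCompartments>\n',
    '<listOfSpecies>\n',
    '<species metaid="PEP" id="PEP" compartment="cyt">\n',
    '<annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
    'xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">\n',
    '<rdf:Description rdf:about="#PEP"><bqbiol:is><rdf:Bag>\n',
    '<rdf:li rdf:resource="urn:miriam:obo.chebi:CHEBI%3A18021"/>\n',
    '</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>\n',
    '</species>\n</listOfSpecies>\n</model>\n</sbml>\n')
}

# parse + featurize a generated corpus into representations
corpus_reps <- function(n, seed, ...) {
  docs <- gen_corpus(n, seed = seed, ...)
  lapply(names(docs), function(id) featurize(parse_model(docs[[id]], id)))
}

ont_fixture <- function() {
  fx <- worked_example_fixture()
  path <- tempfile(fileext = ".obo")
  writeLines(fx$obo, path)
  on.exit(unlink(path))
  load_obo(path)
}
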