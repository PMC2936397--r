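# Run code with its own RNG stream, leaving the caller's RNG state intact.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

rdf_block <- function(about, body) {
  paste0(
    "<annotation>\n",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\" ",
    "xmlns:dc=\"http://purl.org/dc/elements/1.1/\" ",
    "xmlns:dcterms=\"http://purl.org/dc/terms/\" ",
    "xmlns:vCard=\"http://www.w3.org/2001/vcard-rdf/3.0#\" ",
    "xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\" ",
    "xmlns:bqmodel=\"http://biomodels.net/model-qualifiers/\">\n",
    "<rdf:Description rdf:about=\"#", about, "\">\n", body,
    "</rdf:Description>\n</rdf:RDF>\n</annotation>\n")
}

qualifier_tag <- function(prefix, qualifier, uris) {
  paste0("<", prefix, ":", qualifier, ">\n<rdf:Bag>\n",
         paste0("<rdf:li rdf:resource=\"", xml_escape(uris), "\"/>\n",
                collapse = ""),
         "</rdf:Bag>\n</", prefix, ":", qualifier, ">\n")
}

# Serialize one model to SBML Level 2 Version 4 text with BioModels-style
# RDF annotations. Element descriptors: data.frames with columns id, name
# and optionally uri, qualifier, prefix (NA uri = unannotated).
sbml_document <- function(id, name, notes = "", authors = character(),
                          created = NA, modified = NA,
                          publication_uri = "", model_uris = NULL,
                          compartments = NULL, species = NULL,
                          reactions = NULL, parameters = NULL) {
  meta <- character()
  if (length(authors)) {
    vc <- vapply(authors, function(a) {
      bits <- strsplit(a, "\\s+")[[1]]
      fam <- bits[length(bits)]
      giv <- paste(bits[-length(bits)], collapse = " ")
      paste0("<rdf:li rdf:parseType=\"Resource\">\n",
             "<vCard:N rdf:parseType=\"Resource\">\n",
             "<vCard:Family>", xml_escape(fam), "</vCard:Family>\n",
             "<vCard:Given>", xml_escape(giv), "</vCard:Given>\n",
             "</vCard:N>\n</rdf:li>\n")
    }, character(1))
    meta <- c(meta, paste0("<dc:creator>\n<rdf:Bag>\n",
                           paste(vc, collapse = ""),
                           "</rdf:Bag>\n</dc:creator>\n"))
  }
  if (!is.na(created))
    meta <- c(meta, paste0(
      "<dcterms:created rdf:parseType=\"Resource\">\n<dcterms:W3CDTF>",
      as.character(created),
      "T00:00:00Z</dcterms:W3CDTF>\n</dcterms:created>\n"))
  if (!is.na(modified))
    meta <- c(meta, paste0(
      "<dcterms:modified rdf:parseType=\"Resource\">\n<dcterms:W3CDTF>",
      as.character(modified),
      "T00:00:00Z</dcterms:W3CDTF>\n</dcterms:modified>\n"))
  if (nzchar(publication_uri))
    meta <- c(meta, qualifier_tag("bqmodel", "isDescribedBy", publication_uri))
  if (!is.null(model_uris) && nrow(model_uris))
    for (i in seq_len(nrow(model_uris)))
      meta <- c(meta, qualifier_tag(model_uris$prefix[i],
                                    model_uris$qualifier[i],
                                    model_uris$uri[i]))
  model_ann <- if (length(meta))
    rdf_block(paste0("metaid_", id), paste(meta, collapse = "")) else ""

  element_xml <- function(tag, df, extra_attr = "") {
    if (is.null(df) || !nrow(df)) return("")
    rows <- vapply(seq_len(nrow(df)), function(i) {
      ann <- ""
      if (!is.null(df$uri) && !is.na(df$uri[i]) && nzchar(df$uri[i]))
        ann <- rdf_block(df$id[i],
                         qualifier_tag(df$prefix[i], df$qualifier[i],
                                       strsplit(df$uri[i], " ")[[1]]))
      nm <- if (!is.na(df$name[i]) && nzchar(df$name[i]))
        paste0(" name=\"", xml_escape(df$name[i]), "\"") else ""
      if (nzchar(ann))
        paste0("<", tag, " metaid=\"", df$id[i], "\" id=\"", df$id[i], "\"",
               nm, extra_attr, ">\n", ann, "</", tag, ">\n")
      else
        paste0("<", tag, " id=\"", df$id[i], "\"", nm, extra_attr, "/>\n")
    }, character(1))
    paste(rows, collapse = "")
  }

  sp_attr <- if (!is.null(species) && nrow(species))
    paste0(" compartment=\"", species$compartment, "\"") else ""
  sp_xml <- if (is.null(species) || !nrow(species)) "" else
    paste(vapply(seq_len(nrow(species)), function(i)
      element_xml("species", species[i, , drop = FALSE], sp_attr[i]),
      character(1)), collapse = "")

  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" level=\"2\" version=\"4\">\n",
    "<model metaid=\"metaid_", id, "\" id=\"", id, "\"",
    if (nzchar(name)) paste0(" name=\"", xml_escape(name), "\"") else "", ">\n",
    if (nzchar(notes))
      paste0("<notes>\n<body xmlns=\"http://www.w3.org/1999/xhtml\">\n<p>",
             xml_escape(notes), "</p>\n</body>\n</notes>\n") else "",
    model_ann,
    if (!is.null(compartments) && nrow(compartments))
      paste0("<listOfCompartments>\n",
             element_xml("compartment", compartments),
             "</listOfCompartments>\n") else "",
    if (nzchar(sp_xml))
      paste0("<listOfSpecies>\n", sp_xml, "</listOfSpecies>\n") else "",
    if (!is.null(parameters) && nrow(parameters))
      paste0("<listOfParameters>\n",
             element_xml("parameter", parameters, " value=\"1\""),
             "</listOfParameters>\n") else "",
    if (!is.null(reactions) && nrow(reactions))
      paste0("<listOfReactions>\n",
             element_xml("reaction", reactions, " reversible=\"false\""),
             "</listOfReactions>\n") else "",
    "</model>\n</sbml>\n")
}

#' Built-in generator vocabulary
#'
#' Small catalogue of biological entities (compounds, cell compartments,
#' processes) with their annotation URNs, used by [gen_corpus()] to name
#' and annotate generated model elements.
#'
#' @return data.frame with columns `kind` (species/compartment/reaction),
#'   `name` and `uri`.
#' @export
builtin_vocabulary <- function() {
  rbind(
    data.frame(kind = "species", stringsAsFactors = FALSE, rbind(
      c(name = "caffeine", uri = "urn:miriam:obo.chebi:CHEBI%3A27732"),
      c("xanthine", "urn:miriam:kegg.compound:C00385"),
      c("glucose", "urn:miriam:obo.chebi:CHEBI%3A17234"),
      c("ATP", "urn:miriam:obo.chebi:CHEBI%3A15422"),
      c("pyruvate", "urn:miriam:obo.chebi:CHEBI%3A15361"),
      c("phosphoenolpyruvate", "urn:miriam:obo.chebi:CHEBI%3A18021"),
      c("calcium ion", "urn:miriam:obo.chebi:CHEBI%3A29108"),
      c("glyoxylate", "urn:miriam:kegg.compound:C00048"),
      c("serotonin", "urn:miriam:obo.chebi:CHEBI%3A28790"),
      c("glutathione", "urn:miriam:obo.chebi:CHEBI%3A16856"),
      c("dioxygen", "urn:miriam:obo.chebi:CHEBI%3A15379"),
      c("water", "urn:miriam:obo.chebi:CHEBI%3A15377"))),
    data.frame(kind = "compartment", stringsAsFactors = FALSE, rbind(
      c(name = "cytosol", uri = "urn:miriam:obo.go:GO%3A0005829"),
      c("nucleus", "urn:miriam:obo.go:GO%3A0005634"),
      c("mitochondrion", "urn:miriam:obo.go:GO%3A0005739"),
      c("extracellular region", "urn:miriam:obo.go:GO%3A0005576"),
      c("gut", "urn:miriam:obo.go:GO%3A0005623"))),
    data.frame(kind = "reaction", stringsAsFactors = FALSE, rbind(
      c(name = "phosphorylation", uri = "urn:miriam:obo.go:GO%3A0016310"),
      c("glycolysis", "urn:miriam:obo.go:GO%3A0006096"),
      c("hexokinase activity", "urn:miriam:obo.go:GO%3A0004396"),
      c("transport", "urn:miriam:obo.go:GO%3A0006810"),
      c("oxidative phosphorylation", "urn:miriam:obo.go:GO%3A0006119"))))
}

#' Lexicon for the built-in vocabulary
#'
#' Maps each built-in URN to a short descriptive keyword stream (name plus
#' generic resource words), so generated corpora can exercise semantic
#' resolution without any external lookup.
#' @return a `lexicon`.
#' @export
builtin_lexicon <- function() {
  v <- builtin_vocabulary()
  as_lexicon(stats::setNames(
    paste(v$name, v$kind, "entry", sub("^urn:miriam:", "", v$uri)), v$uri))
}

#' Generate a deterministic synthetic corpus of annotated SBML models
#'
#' Each model receives randomly drawn species, compartments and reactions
#' named from the vocabulary; a fraction `annotation_density` of the
#' elements carry the matching URN under a qualifier drawn from
#' `qualifier_mix`. Authors, dates and notes are drawn deterministically
#' from the seed: the same arguments always yield byte-identical SBML.
#'
#' @param n_models number of models (>= 1).
#' @param seed integer seed; the generator threads all randomness through
#'   it and restores the caller's RNG state.
#' @param annotation_density fraction of eligible elements annotated, in
#'   \\[0, 1\\].
#' @param qualifier_mix named probability vector over qualifier names.
#' @param vocabulary data.frame as [builtin_vocabulary()].
#' @param dir optional directory; when given, one `<model_id>.xml` file per
#'   model is written there.
#' @return named character vector, model_id -> SBML document text.
#' @export
gen_corpus <- function(n_models, seed = 1L, annotation_density = 0.8,
                       qualifier_mix = c(is = 0.5, isVersionOf = 0.2,
                                         hasPart = 0.1, hasVersion = 0.1,
                                         isHomologTo = 0.1),
                       vocabulary = builtin_vocabulary(), dir = NULL) {
  if (n_models < 1) stop("n_models must be >= 1")
  stopifnot(annotation_density >= 0, annotation_density <= 1,
            all(names(qualifier_mix) %in% miriam_qualifiers()),
            nrow(vocabulary) > 0)
  surnames <- c("Somogyi", "Tyson", "Goldbeter", "Novak", "Leloup",
                "Hodgkin", "Huxley", "Edelstein", "Kholodenko", "Curien")
  given <- c("Anna", "Bela", "Chris", "Dora", "Emil", "Flora")
  note_words <- c("kinetic", "model", "of", "signalling", "pathway",
                  "oscillations", "in", "cells", "metabolism", "dynamics",
                  "regulation", "network")
  with_local_seed(seed, {
    docs <- character(n_models)
    ids <- sprintf("MDL%04d", seq_len(n_models))
    for (i in seq_len(n_models)) {
      pick <- function(kind, n) {
        pool <- vocabulary[vocabulary$kind == kind, , drop = FALSE]
        pool[sample.int(nrow(pool), min(n, nrow(pool))), , drop = FALSE]
      }
      n_sp <- sample(1:4, 1)
      n_cp <- sample(1:2, 1)
      n_rx <- sample(0:3, 1)
      sp <- pick("species", n_sp)
      cp <- pick("compartment", n_cp)
      rx <- pick("reaction", n_rx)
      mk <- function(df, tag) {
        if (!nrow(df)) return(NULL)
        ann <- stats::runif(nrow(df)) < annotation_density
        qual <- sample(names(qualifier_mix), nrow(df), replace = TRUE,
                       prob = qualifier_mix)
        data.frame(id = sprintf("%s%d_%d", tag, i, seq_len(nrow(df))),
                   name = df$name,
                   uri = ifelse(ann, df$uri, NA_character_),
                   qualifier = qual, prefix = "bqbiol",
                   stringsAsFactors = FALSE)
      }
      spd <- mk(sp, "s")
      cpd <- mk(cp, "c")
      rxd <- mk(rx, "r")
      if (!is.null(spd)) spd$compartment <- cpd$id[1]
      author <- paste(sample(given, 1), sample(surnames, 1))
      created <- as.Date("2005-01-01") + sample.int(1800, 1)
      modified <- created + sample.int(300, 1)
      notes <- paste(sample(note_words, 6, replace = TRUE), collapse = " ")
      pub <- sprintf("urn:miriam:pubmed:%d", 10000000 + sample.int(9999999, 1))
      if (stats::runif(1) >= annotation_density) pub <- ""
      docs[i] <- sbml_document(
        id = ids[i],
        name = paste(sp$name[1], "model", i),
        notes = notes, authors = author,
        created = created, modified = modified,
        publication_uri = pub,
        compartments = cpd, species = spd, reactions = rxd)
    }
    names(docs) <- ids
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(docs))
        writeLines(docs[i], file.path(dir, paste0(ids[i], ".xml")),
                   useBytes = TRUE)
    }
    docs
  })
}

# Table of the four URIs of the packaged caffeine example with their
# keyword streams (offline stand-in for live ChEBI/KEGG resolution).
caffeine_lexicon <- function() {
  as_lexicon(c(
    "urn:miriam:obo.chebi:CHEBI%3A27732" = paste(
      "caffeine chebi 27732 chebi home advanced search browse ontology",
      "periodic molecules chebi main caffeine chebi 116485 central nervous",
      "system stimulant caffeine ryanodine receptor modulator mutagen",
      "1,3,7-trimethyl-3,7-dihydro-1H-purine-2,6-dion msdchem d00528 kegg",
      "drug"),
    "urn:miriam:kegg.compound:C07481" = paste(
      "kegg compound c07481 entry c07481 compound name caffeine",
      "1,3,7-trimethylxanthine formula c8h10n4o2 mass 194.0804 structure",
      "remark d00528 comment source coffea arabica tax 13443 xanthines",
      "reaction r07920 r07921 27732 knapsack c00001492"),
    "urn:miriam:kegg.compound:C00385" = paste(
      "kegg compound c00385 name xanthine formula c5h4n4o2 mass 152.0334",
      "ko00230 purine metabolism caffeine metabolism"),
    "urn:miriam:kegg.compound:C00048" = paste(
      "kegg compound c00048 entry c00048 glyoxylate glyoxylic acid formula",
      "c2h2o3 mass 74.0004 structure reaction r00013 r00364 purine",
      "metabolism path ko00232 caffeine metabolism glycine serine",
      "threonine metabolism")))
}

# Mini ontology: caffeine --is_a--> methylxanthine --is_a--> xanthine,
# plus a purine root; used for expansion tests and the worked example.
caffeine_obo <- function() {
  paste(
    "format-version: 1.2",
    "ontology: mrank/caffeine-mini",
    "",
    "[Term]",
    "id: CHEBI:27732",
    "name: caffeine",
    "synonym: \"1,3,7-trimethylxanthine\" EXACT []",
    "is_a: CHEBI:25348 ! methylxanthine",
    "",
    "[Term]",
    "id: CHEBI:25348",
    "name: methylxanthine",
    "is_a: CHEBI:15318 ! xanthine",
    "",
    "[Term]",
    "id: CHEBI:15318",
    "name: xanthine",
    "is_a: CHEBI:26401 ! purines",
    "",
    "[Term]",
    "id: CHEBI:26401",
    "name: purines",
    "", sep = "\n")
}

#' The packaged caffeine worked example
#'
#' A three-model corpus, lexicon and mini-ontology reproducing the
#' caffeine-in-the-gut retrieval scenario: model A
#' (`BIOMD0000000241`) links the ChEBI and KEGG caffeine URIs via
#' `bqbiol:is` and encodes the compartment "gut"; model B
#' (`BIOMD0000000015`) links the KEGG xanthine URI via `bqbiol:is`; model C
#' (`BIOMD0000000220`, a synthetic stand-in for a weakly related model)
#' links the xanthine and glyoxylate URIs only via `bqbiol:isVersionOf`.
#' Under the packaged weights the example query ranks A above B above C.
#'
#' @param dir optional directory; when given, the SBML files, the lexicon
#'   (`lexicon.json`) and the ontology (`ontology.obo`) are written there.
#' @return list with `sbml` (named character vector of SBML documents),
#'   `lexicon` (a `lexicon`), `obo` (OBO text) and `query` (the example
#'   query expression).
#' @export
worked_example_fixture <- function(dir = NULL) {
  mk_species <- function(id, name, comp, uri, qualifier)
    data.frame(id = id, name = name, compartment = comp, uri = uri,
               qualifier = qualifier, prefix = "bqbiol",
               stringsAsFactors = FALSE)
  a <- sbml_document(
    id = "BIOMD0000000241", name = "caffeine gut absorption",
    notes = "absorption and metabolism of caffeine in the digestive tract",
    authors = "Lena Vogel", created = as.Date("2009-06-15"),
    modified = as.Date("2009-08-02"),
    publication_uri = "urn:miriam:pubmed:19696443",
    compartments = data.frame(id = "gut_c", name = "gut",
                              uri = "urn:miriam:obo.go:GO%3A0005623",
                              qualifier = "is", prefix = "bqbiol",
                              stringsAsFactors = FALSE),
    species = rbind(
      mk_species("caf", "caffeine", "gut_c",
                 "urn:miriam:obo.chebi:CHEBI%3A27732 urn:miriam:kegg.compound:C07481",
                 "is"),
      mk_species("px", "paraxanthine", "gut_c", NA, "is")))
  b <- sbml_document(
    id = "BIOMD0000000015", name = "purine degradation",
    notes = "xanthine oxidation in purine metabolism",
    authors = "Marta Keller", created = as.Date("2009-03-20"),
    modified = as.Date("2009-04-11"),
    publication_uri = "urn:miriam:pubmed:15985460",
    compartments = data.frame(id = "cyt", name = "cytosol",
                              uri = NA, qualifier = "is", prefix = "bqbiol",
                              stringsAsFactors = FALSE),
    species = mk_species("xan", "xanthine", "cyt",
                         "urn:miriam:kegg.compound:C00385", "is"))
  c_ <- sbml_document(
    id = "BIOMD0000000220", name = "purine salvage variant",
    notes = "variant pathway weakly related to methylxanthine turnover",
    authors = "Jonas Brandt", created = as.Date("2010-01-05"),
    modified = as.Date("2010-02-14"),
    publication_uri = "urn:miriam:pubmed:20130715",
    compartments = data.frame(id = "cyt2", name = "cytosol",
                              uri = NA, qualifier = "is", prefix = "bqbiol",
                              stringsAsFactors = FALSE),
    species = rbind(
      mk_species("x1", "oxopurine pool", "cyt2",
                 "urn:miriam:kegg.compound:C00385", "isVersionOf"),
      mk_species("g1", "glyoxylate", "cyt2",
                 "urn:miriam:kegg.compound:C00048", "isVersionOf")))
  sbml <- c(BIOMD0000000241 = a, BIOMD0000000015 = b, BIOMD0000000220 = c_)
  out <- list(
    sbml = sbml, lexicon = caffeine_lexicon(), obo = caffeine_obo(),
    query = paste("+species@is:(caffeine) compartment:(gut)",
                  "-author:(john doe) date:([01/01/2009 - *])"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(sbml))
      writeLines(sbml[[id]], file.path(dir, paste0(id, ".xml")),
                 useBytes = TRUE)
    jsonlite::write_json(as.list(unclass(out$lexicon)),
                         file.path(dir, "lexicon.json"), auto_unbox = TRUE)
    writeLines(out$obo, file.path(dir, "ontology.obo"), useBytes = TRUE)
  }
  out
}

#' Build the search engine for the worked example
#'
#' Convenience wrapper: parses the three packaged models and bundles them
#' with the packaged lexicon, mini-ontology and default weights.
#' @return a `model_search_engine`.
#' @export
worked_example_engine <- function() {
  fx <- worked_example_fixture()
  obo_path <- tempfile(fileext = ".obo")
  writeLines(fx$obo, obo_path, useBytes = TRUE)
  on.exit(unlink(obo_path))
  models <- lapply(names(fx$sbml), function(id)
    parse_model(fx$sbml[[id]], model_id = id))
  build_engine(models, lexicon = fx$lexicon,
               ontologies = list(load_obo(obo_path)))
}
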