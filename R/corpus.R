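# Namespaces used inside SBML RDF annotation blocks (BioModels style).
sbml_ns <- c(
  rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  bqbiol  = "http://biomodels.net/biology-qualifiers/",
  bqmodel = "http://biomodels.net/model-qualifiers/",
  dc      = "http://purl.org/dc/elements/1.1/",
  dcterms = "http://purl.org/dc/terms/",
  vCard   = "http://www.w3.org/2001/vcard-rdf/3.0#"
)

empty_annotation_df <- function() {
  data.frame(uri = character(), data_type = character(),
             identifier = character(), qualifier = character(),
             prefix = character(), stringsAsFactors = FALSE)
}

# Pull (qualifier, URN) pairs out of a node's RDF annotation block.
# Unknown qualifier names and malformed URNs are skipped with a warning.
rdf_annotations <- function(node, where = "element") {
  out <- empty_annotation_df()
  for (prefix in c("bqbiol", "bqmodel")) {
    quals <- xml2::xml_find_all(node,
      paste0("./*[local-name()='annotation']//", prefix, ":*"), sbml_ns)
    for (q in quals) {
      qname <- xml2::xml_name(q)
      lis <- xml2::xml_find_all(q, ".//rdf:li", sbml_ns)
      res <- character()
      for (li in lis) {
        at <- xml2::xml_attrs(li)
        hit <- at[grepl("(^|:)resource$", names(at))]
        if (length(hit)) res <- c(res, unname(hit[1]))
      }
      if (!length(res)) next
      if (!qname %in% miriam_qualifiers()) {
        warning("skipping unknown qualifier '", prefix, ":", qname,
                "' on ", where, call. = FALSE)
        next
      }
      urn <- normalize_urn(res)
      if (any(!urn$valid)) {
        warning("skipping non-MIRIAM resource(s) on ", where, ": ",
                paste(res[!urn$valid], collapse = ", "), call. = FALSE)
        urn <- urn[urn$valid, , drop = FALSE]
      }
      if (nrow(urn))
        out <- rbind(out, data.frame(uri = urn$uri, data_type = urn$data_type,
                                     identifier = urn$identifier,
                                     qualifier = qname, prefix = prefix,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

# SBO term attribute treated as one more annotation (namespace biomodels.sbo,
# qualifier is).
sbo_annotation <- function(node) {
  sbo <- xml2::xml_attr(node, "sboTerm")
  if (is.na(sbo) || !nzchar(sbo)) return(empty_annotation_df())
  data.frame(uri = paste0("urn:miriam:biomodels.sbo:", percent_encode_id(sbo)),
             data_type = "biomodels.sbo", identifier = sbo,
             qualifier = "is", prefix = "bqbiol", stringsAsFactors = FALSE)
}

element_kinds <- c(species = "species", compartment = "compartment",
                   reaction = "reaction", parameter = "parameter",
                   event = "event", functionDefinition = "function")

#' Parse an SBML document into an annotated model
#'
#' Reads an SBML (Level 2 dialect) document, collecting one model element
#' per species, compartment, reaction, global parameter, event and function
#' definition, together with all RDF-encoded MIRIAM annotation URNs, model
#' notes, name, creators and creation/modification dates.
#'
#' @param document path to an SBML file, or a length-1 character string of
#'   SBML XML.
#' @param model_id identifier for the model within a corpus; defaults to the
#'   model element's `id` attribute (falling back to the file name).
#' @return object of class `annotated_model`.
#' @export
parse_model <- function(document, model_id = NULL) {
  is_path <- length(document) == 1L && !grepl("<", document, fixed = TRUE)
  label <- if (is_path) document else "<inline SBML>"
  doc <- tryCatch(xml2::read_xml(document),
                  error = function(e) stop("cannot parse '", label, "': ",
                                           conditionMessage(e), call. = FALSE))
  root_ns <- unlist(xml2::xml_ns(doc))
  if (!any(grepl("sbml", root_ns, fixed = TRUE)))
    stop("'", label, "' does not claim an SBML namespace", call. = FALSE)
  model <- xml2::xml_find_first(doc, "/*[local-name()='sbml']/*[local-name()='model']")
  if (inherits(model, "xml_missing"))
    stop("no SBML model element in '", label, "'", call. = FALSE)

  mid <- model_id
  if (is.null(mid)) mid <- xml2::xml_attr(model, "id")
  if (is.na(mid) || !nzchar(mid))
    mid <- if (is_path) tools::file_path_sans_ext(basename(document)) else
      stop("model in '", label, "' has no id; supply model_id", call. = FALSE)

  name <- xml2::xml_attr(model, "name")
  if (is.na(name)) name <- ""
  notes <- xml2::xml_find_first(model, "./*[local-name()='notes']")
  notes_text <- if (inherits(notes, "xml_missing")) "" else
    trimws(gsub("\\s+", " ", xml2::xml_text(notes)))

  list_containers <- c(species = "listOfSpecies",
                       compartment = "listOfCompartments",
                       reaction = "listOfReactions",
                       parameter = "listOfParameters",
                       event = "listOfEvents",
                       functionDefinition = "listOfFunctionDefinitions")
  elements <- list()
  for (tag in names(element_kinds)) {
    lof <- list_containers[[tag]]
    nodes <- xml2::xml_find_all(model, paste0(
      "./*[local-name()='", lof, "']/*[local-name()='", tag, "']"))
    for (nd in nodes) {
      eid <- xml2::xml_attr(nd, "id")
      if (is.na(eid) || !nzchar(eid)) next
      ename <- xml2::xml_attr(nd, "name")
      if (is.na(ename)) ename <- ""
      ann <- rbind(rdf_annotations(nd, paste0(tag, " '", eid, "'")),
                   sbo_annotation(nd))
      elements[[length(elements) + 1L]] <- structure(
        list(element_kind = unname(element_kinds[tag]), element_id = eid,
             element_name = ename, annotations = ann),
        class = "model_element")
    }
  }

  model_ann <- rbind(rdf_annotations(model, "model"), sbo_annotation(model))

  created <- xml2::xml_find_first(model,
    "./*[local-name()='annotation']//dcterms:created/dcterms:W3CDTF", sbml_ns)
  modified <- xml2::xml_find_first(model,
    "./*[local-name()='annotation']//dcterms:modified/dcterms:W3CDTF", sbml_ns)
  creation_date <- parse_flex_date(
    if (inherits(created, "xml_missing")) NA_character_ else xml2::xml_text(created))
  modification_date <- parse_flex_date(
    if (inherits(modified, "xml_missing")) NA_character_ else xml2::xml_text(modified))

  vcards <- xml2::xml_find_all(model,
    "./*[local-name()='annotation']//dc:creator//vCard:N", sbml_ns)
  persons <- data.frame(role = character(), name = character(),
                        stringsAsFactors = FALSE)
  for (vc in vcards) {
    fam <- xml2::xml_find_first(vc, "./vCard:Family", sbml_ns)
    giv <- xml2::xml_find_first(vc, "./vCard:Given", sbml_ns)
    nm <- trimws(paste(
      if (inherits(giv, "xml_missing")) "" else xml2::xml_text(giv),
      if (inherits(fam, "xml_missing")) "" else xml2::xml_text(fam)))
    if (nzchar(nm))
      persons <- rbind(persons, data.frame(role = "author", name = nm,
                                           stringsAsFactors = FALSE))
  }

  # model-level isDescribedBy links identify the reference publication
  pub_idx <- model_ann$qualifier == "isDescribedBy"
  publication <- list(
    uri = if (any(pub_idx)) model_ann$uri[which(pub_idx)[1]] else "",
    text = "")

  structure(list(
    model_id = mid, source_format = "SBML-L2", name = name,
    description_text = notes_text, elements = elements,
    model_level_annotations = model_ann,
    creation_date = creation_date, modification_date = modification_date,
    persons = persons, publication = publication,
    admin = list(file_path = if (is_path) document else "",
                 additional_ids = character()),
    content = character()
  ), class = "annotated_model")
}

#' @export
print.annotated_model <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, "", "element_kind")
  n_ann <- sum(vapply(x$elements, function(e) nrow(e$annotations), 0L)) +
    nrow(x$model_level_annotations)
  cat("<annotated_model>", x$model_id,
      if (nzchar(x$name)) paste0("(", x$name, ")") else "", "\n")
  cat("  elements:", length(x$elements),
      paste0("[", paste(names(table(kinds)), table(kinds), sep = ":",
                        collapse = " "), "]"), "\n")
  cat("  annotations:", n_ann, "\n")
  invisible(x)
}

#' Flatten all annotations of a model
#'
#' @param model an `annotated_model`.
#' @return data.frame with one row per annotation occurrence (duplicates
#'   retained): `element_kind` (`"model"` for model-level annotations),
#'   `element_id`, `uri` (normalized URN), `data_type`, `identifier`
#'   (percent-decoded), `qualifier`, `prefix`.
#' @export
extract_annotations <- function(model) {
  stopifnot(inherits(model, "annotated_model"))
  parts <- list(
    if (nrow(model$model_level_annotations))
      cbind(data.frame(element_kind = "model", element_id = model$model_id,
                       stringsAsFactors = FALSE),
            model$model_level_annotations))
  for (el in model$elements) {
    if (nrow(el$annotations))
      parts[[length(parts) + 1L]] <-
        cbind(data.frame(element_kind = el$element_kind,
                         element_id = el$element_id, stringsAsFactors = FALSE),
              el$annotations)
  }
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts))
    return(cbind(data.frame(element_kind = character(),
                            element_id = character(), stringsAsFactors = FALSE),
                 empty_annotation_df()))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Split a model into feature-classified term and URI assignments
#'
#' Maps an annotated model onto the feature schema: element names (ids when
#' the name is empty) are tokenized into the matching description feature;
#' annotation URNs go to the matching URI feature with their qualifiers;
#' persons, publication, dates, user content and administrative fields map
#' to their features. Empty features are omitted.
#'
#' @param model an `annotated_model`.
#' @param schema a `feature_schema`; defaults to [default_feature_schema()].
#' @return object of class `model_representation`: list with `model_id`,
#'   `assignments` (named list, feature -> lowercase token vector),
#'   `uri_assignments` (named list, feature -> data.frame(uri, qualifier,
#'   prefix)) and `dates` (named list, feature -> Date).
#' @export
featurize <- function(model, schema = default_feature_schema()) {
  stopifnot(inherits(model, "annotated_model"))
  assignments <- list()
  uri_assignments <- list()
  dates <- list()

  add_terms <- function(feature, tokens) {
    if (length(tokens))
      assignments[[feature]] <<- c(assignments[[feature]], tokens)
  }
  add_uris <- function(feature, ann) {
    if (!is.null(ann) && nrow(ann)) {
      df <- ann[, c("uri", "qualifier", "prefix")]
      uri_assignments[[feature]] <<- rbind(uri_assignments[[feature]], df)
    }
  }

  add_terms("modelName", tokenize(model$name))
  add_terms("modelDescription", tokenize(model$description_text))
  for (el in model$elements) {
    toks <- tokenize(el$element_name)
    if (!length(toks)) toks <- tokenize(el$element_id)
    add_terms(el$element_kind, toks)
    add_uris(paste0(el$element_kind, "URI"), el$annotations)
  }
  ml <- model$model_level_annotations
  if (nrow(ml)) {
    pub <- ml$qualifier == "isDescribedBy"
    add_uris("publicationURI", ml[pub, , drop = FALSE])
    add_uris("modelURI", ml[!pub, , drop = FALSE])
  }
  if (nrow(model$persons))
    for (role in unique(model$persons$role))
      add_terms(role, tokenize(model$persons$name[model$persons$role == role]))
  add_terms("publicationText", tokenize(model$publication$text))
  add_terms("content", tokenize(model$content))
  add_terms("id", tokenize(model$model_id))
  add_terms("additionalId", tokenize(model$admin$additional_ids))
  add_terms("path", tokenize(model$admin$file_path))
  if (!is.na(model$creation_date)) dates[["creationDate"]] <- model$creation_date
  if (!is.na(model$modification_date))
    dates[["modificationDate"]] <- model$modification_date

  known <- schema$feature
  bad <- setdiff(c(names(assignments), names(uri_assignments), names(dates)), known)
  if (length(bad)) stop("features not in schema: ", paste(bad, collapse = ", "))
  uri_assignments <- lapply(uri_assignments, function(df) {
    rownames(df) <- NULL
    df
  })
  structure(list(model_id = model$model_id, assignments = assignments,
                 uri_assignments = uri_assignments, dates = dates),
            class = "model_representation")
}

#' @export
print.model_representation <- function(x, ...) {
  cat("<model_representation>", x$model_id, "\n")
  for (f in names(x$assignments))
    cat("  ", f, ": ", paste(utils::head(x$assignments[[f]], 8), collapse = " "),
        if (length(x$assignments[[f]]) > 8) " ..." else "", "\n", sep = "")
  for (f in names(x$uri_assignments))
    cat("  ", f, ": ", nrow(x$uri_assignments[[f]]), " URI(s)\n", sep = "")
  invisible(x)
}
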