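#' Default feature schema
#'
#' The indexed attributes of a model, grouped into content-related
#' dimensions. Description features hold tokenized text, URI features hold
#' qualifier-typed annotation URNs, date features hold day-precision dates.
#'
#' @return object of class `feature_schema`: a data.frame with columns
#'   `feature`, `dimension` (one of constituents, persons, dates,
#'   publication, user_content, administrative) and `kind` (term, uri,
#'   date).
#' @export
default_feature_schema <- function() {
  s <- rbind(
    data.frame(feature = c("modelName", "species", "compartment", "reaction",
                           "parameter", "event", "function", "modelDescription"),
               dimension = "constituents", kind = "term"),
    data.frame(feature = c("modelURI", "speciesURI", "compartmentURI",
                           "reactionURI", "parameterURI", "eventURI",
                           "functionURI"),
               dimension = "constituents", kind = "uri"),
    data.frame(feature = c("author", "encoder", "submitter"),
               dimension = "persons", kind = "term"),
    data.frame(feature = "publicationURI", dimension = "publication", kind = "uri"),
    data.frame(feature = "publicationText", dimension = "publication", kind = "term"),
    data.frame(feature = "content", dimension = "user_content", kind = "term"),
    data.frame(feature = c("creationDate", "modificationDate"),
               dimension = "dates", kind = "date"),
    data.frame(feature = c("id", "additionalId", "path"),
               dimension = "administrative", kind = "term")
  )
  stopifnot(!anyDuplicated(s$feature))
  class(s) <- c("feature_schema", "data.frame")
  s
}

#' Dimension importance labels
#'
#' Qualitative importance attached to each information dimension; kept as
#' documentation alongside the numeric per-feature weights.
#' @return named character vector, dimension -> label.
#' @export
dimension_importance <- function() {
  c(administrative = "low", persons = "medium", dates = "low",
    publication = "high", constituents = "very high",
    user_content = "very high")
}

# description feature -> sibling URI feature, for semantic query expansion
uri_feature_for <- function(feature) {
  map <- c(modelName = "modelURI", species = "speciesURI",
           compartment = "compartmentURI", reaction = "reactionURI",
           parameter = "parameterURI", event = "eventURI",
           `function` = "functionURI")
  unname(map[feature])
}

#' Default weight configuration
#'
#' Reads the packaged `feature_weights.yaml` and `qualifier_weights.yaml`
#' defaults, or user-supplied files in the same format.
#'
#' @param feature_file,qualifier_file paths to YAML files mapping feature /
#'   qualifier names to positive numeric weights; defaults to the packaged
#'   configuration.
#' @param schema feature schema the configuration must cover.
#' @return object of class `weight_config`: list with `feature_weights` and
#'   `qualifier_weights` (named numeric vectors) and `dimension_importance`.
#' @export
weight_config <- function(feature_file = NULL, qualifier_file = NULL,
                          schema = default_feature_schema()) {
  if (is.null(feature_file))
    feature_file <- system.file("extdata", "feature_weights.yaml",
                                package = "mrank", mustWork = TRUE)
  if (is.null(qualifier_file))
    qualifier_file <- system.file("extdata", "qualifier_weights.yaml",
                                  package = "mrank", mustWork = TRUE)
  fw <- unlist(yaml::read_yaml(feature_file))
  qw <- unlist(yaml::read_yaml(qualifier_file))
  storage.mode(fw) <- "double"
  storage.mode(qw) <- "double"
  missing_f <- setdiff(schema$feature, names(fw))
  if (length(missing_f))
    stop("feature weights missing for: ", paste(missing_f, collapse = ", "))
  missing_q <- setdiff(miriam_qualifiers(), names(qw))
  if (length(missing_q))
    stop("qualifier weights missing for: ", paste(missing_q, collapse = ", "))
  if (any(fw <= 0) || any(qw <= 0)) stop("weights must be positive")
  structure(list(feature_weights = fw, qualifier_weights = qw,
                 dimension_importance = dimension_importance()),
            class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat("<weight_config>", length(x$feature_weights), "feature weights,",
      length(x$qualifier_weights), "qualifier weights\n")
  invisible(x)
}
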