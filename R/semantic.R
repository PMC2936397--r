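#' Load an offline URI lexicon
#'
#' A lexicon maps annotation URNs to descriptive text (names, synonyms,
#' formulas, cross-reference keywords) and stands in for live resolution of
#' URIs against external web resources. Accepted formats: a JSON object
#' (`{"urn:...": "text", ...}`) or a two-column tab-separated file.
#'
#' @param path file path.
#' @return object of class `lexicon`: named character vector, normalized
#'   URN -> description text.
#' @export
read_lexicon <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path)
    lex <- vapply(raw, paste, character(1), collapse = " ")
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
    if (ncol(tab) < 2) stop("lexicon TSV needs two columns: uri, text")
    lex <- stats::setNames(as.character(tab[[2]]), tab[[1]])
  }
  as_lexicon(lex)
}

#' Construct a lexicon from a named character vector
#' @param x named character vector, URN -> description text.
#' @return a `lexicon` with normalized URN names.
#' @export
as_lexicon <- function(x) {
  stopifnot(is.character(x))
  if (!length(x))
    return(structure(stats::setNames(character(), character()),
                     class = "lexicon"))
  stopifnot(!is.null(names(x)))
  urn <- normalize_urn(names(x))
  if (any(!urn$valid))
    stop("invalid URN(s) in lexicon: ",
         paste(names(x)[!urn$valid], collapse = ", "))
  structure(stats::setNames(unname(x), urn$uri), class = "lexicon")
}

qualifier_key <- function(prefix, qualifier) paste(prefix, qualifier, sep = "_")
qualifier_name_of_key <- function(key) sub("^(bqbiol|bqmodel)_", "", key)

#' Build the semantic index
#'
#' One entry per distinct URI occurring in any model of the corpus. Each
#' entry records, per vocabulary-prefixed qualifier (e.g. `bqbiol_is`), the
#' set of models linking that URI, plus the tokenized descriptive content
#' resolved from the lexicon (empty when the lexicon does not know the URI).
#'
#' @param reps list of `model_representation` objects.
#' @param lexicon a `lexicon` (may be empty).
#' @return object of class `semantic_index`.
#' @export
build_semantic_index <- function(reps, lexicon = as_lexicon(character(0))) {
  entries <- list()
  for (rep in reps) {
    stopifnot(inherits(rep, "model_representation"))
    for (f in names(rep$uri_assignments)) {
      ua <- rep$uri_assignments[[f]]
      for (i in seq_len(nrow(ua))) {
        uri <- ua$uri[i]
        key <- qualifier_key(ua$prefix[i], ua$qualifier[i])
        e <- entries[[uri]]
        if (is.null(e)) e <- list(uri = uri, links = list(),
                                  content_terms = character())
        e$links[[key]] <- sort(unique(c(e$links[[key]], rep$model_id)))
        entries[[uri]] <- e
      }
    }
  }
  for (uri in names(entries))
    if (uri %in% names(lexicon))
      entries[[uri]]$content_terms <- tokenize(unname(lexicon[[uri]]))
  rebuild_semantic_index(entries)
}

#' @export
print.semantic_index <- function(x, ...) {
  cat("<semantic_index>", x$doc_count, "URI(s)\n")
  invisible(x)
}

si_idf <- function(index, term) {
  d <- if (exists(term, index$df, inherits = FALSE)) get(term, index$df) else 0L
  1 + log(index$doc_count / (1 + d))
}

#' Resolve keywords to a weighted, ranked list of URIs
#'
#' Treats each semantic-index entry's content as a document and scores it by
#' cosine similarity between the tf-idf vectors of the query terms and the
#' content (tf = sqrt of count, idf = 1 + ln(N/(1 + df)) over semantic
#' entries). Entries with score 0 are dropped. When `qualifier_filter` is
#' given, only entries linked to at least one model under one of the listed
#' qualifier names are kept (matching is vocabulary-agnostic: `is` accepts
#' both `bqbiol_is` and `bqmodel_is`). Ties are broken by ascending URI.
#'
#' @param index a `semantic_index`.
#' @param terms character vector of query tokens (a multiset; duplicates
#'   raise the term frequency).
#' @param qualifier_filter optional character vector of qualifier names.
#' @param k maximum number of URIs returned (>= 1).
#' @return data.frame with columns `uri`, `weight` (in (0, 1], non-increasing)
#'   and `matched_qualifiers` (list column of qualifier names).
#' @export
resolve_terms <- function(index, terms, qualifier_filter = NULL, k = 10L) {
  stopifnot(inherits(index, "semantic_index"), k >= 1)
  terms <- tokenize(terms)
  empty <- data.frame(uri = character(), weight = numeric())
  empty$matched_qualifiers <- list()
  if (!length(terms) || index$doc_count == 0L) return(empty)

  qcnt <- table(terms)
  qterms <- names(qcnt)
  qw <- sqrt(as.numeric(qcnt)) * vapply(qterms, si_idf, 0, index = index)
  qnorm <- sqrt(sum(qw^2))

  rows <- list()
  for (e in index$entries) {
    qnames <- unique(qualifier_name_of_key(names(e$links)))
    if (!is.null(qualifier_filter)) {
      qnames <- intersect(qnames, qualifier_filter)
      if (!length(qnames)) next
    }
    uri <- e$uri
    if (!length(e$content_terms) || index$norms[[uri]] == 0) next
    dcnt <- table(e$content_terms)
    common <- intersect(qterms, names(dcnt))
    if (!length(common)) next
    dw <- sqrt(as.numeric(dcnt[common])) *
      vapply(common, si_idf, 0, index = index)
    score <- sum(qw[match(common, qterms)] * dw) / (qnorm * index$norms[[uri]])
    if (score <= 0) next
    rows[[length(rows) + 1L]] <- list(uri = uri, weight = min(score, 1),
                                      matched_qualifiers = qnames)
  }
  if (!length(rows)) return(empty)
  out <- data.frame(uri = vapply(rows, `[[`, "", "uri"),
                    weight = vapply(rows, `[[`, 0, "weight"),
                    stringsAsFactors = FALSE)
  out$matched_qualifiers <- lapply(rows, `[[`, "matched_qualifiers")
  out <- out[order(-out$weight, out$uri), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Look up the models linked to a URI
#'
#' @param index a `semantic_index`.
#' @param uri annotation URN (normalized on the fly).
#' @param qualifier optional qualifier name; when given, only links under
#'   that qualifier (in either vocabulary) are considered.
#' @return sorted character vector of model ids (empty for unknown URIs).
#' @export
lookup_models <- function(index, uri, qualifier = NULL) {
  stopifnot(inherits(index, "semantic_index"))
  urn <- normalize_urn(uri)
  if (!urn$valid[1]) return(character())
  e <- index$entries[[urn$uri[1]]]
  if (is.null(e)) return(character())
  keys <- names(e$links)
  if (!is.null(qualifier))
    keys <- keys[qualifier_name_of_key(keys) %in% qualifier]
  sort(unique(unlist(e$links[keys], use.names = FALSE)))
}

#' Serialize a semantic index to JSON
#'
#' One JSON object per entry (`uri`, `links`, `content_terms`); tf-idf
#' statistics are recomputed on load.
#' @param index a `semantic_index`.
#' @param path output file path.
#' @export
write_semantic_index <- function(index, path) {
  stopifnot(inherits(index, "semantic_index"))
  objs <- lapply(unname(index$entries), function(e)
    list(uri = e$uri, links = e$links, content_terms = e$content_terms))
  jsonlite::write_json(objs, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' Read a semantic index written by [write_semantic_index()]
#' @param path JSON file path.
#' @return a `semantic_index`.
#' @export
read_semantic_index <- function(path) {
  objs <- jsonlite::read_json(path)
  entries <- list()
  lex <- character()
  for (o in objs) {
    entries[[o$uri]] <- list(
      uri = o$uri,
      links = lapply(o$links, function(v) unlist(v, use.names = FALSE)),
      content_terms = unlist(o$content_terms, use.names = FALSE) %||% character())
  }
  rebuild_semantic_index(entries)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recompute df/norms from raw entries (shared by read_semantic_index)
rebuild_semantic_index <- function(entries) {
  if (length(entries)) entries <- entries[order(names(entries))]
  n <- length(entries)
  df <- new.env(parent = emptyenv())
  for (e in entries) for (t in unique(e$content_terms))
    assign(t, (if (exists(t, df, inherits = FALSE)) get(t, df) else 0L) + 1L, df)
  idf <- function(t) {
    d <- if (exists(t, df, inherits = FALSE)) get(t, df) else 0L
    1 + log(n / (1 + d))
  }
  norms <- vapply(entries, function(e) {
    if (!length(e$content_terms)) return(0)
    cnt <- table(e$content_terms)
    sqrt(sum((sqrt(cnt) * vapply(names(cnt), idf, 0))^2))
  }, 0)
  structure(list(entries = entries, doc_count = n, df = df, norms = norms),
            class = "semantic_index")
}
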