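#' Parse a query expression
#'
#' Grammar: whitespace-separated clauses of the form
#' `[+|-]feature[@qualifier[,qualifier...]]:(term term^boost ...)`;
#' date clauses `date:([start - end])` with `*` for an open end and dates in
#' `dd/MM/yyyy` or ISO `yyyy-MM-dd` (`date` is an alias for `creationDate`).
#' `+` marks a MUST clause, `-` MUST_NOT, no prefix SHOULD. Terms may end
#' in `*` for prefix matching. A query containing no clause syntax at all is
#' treated as free text searched across all term features as SHOULD clauses.
#' Clause features must be pairwise distinct.
#'
#' @param text query expression.
#' @param schema a `feature_schema`.
#' @return object of class `mrank_query`: list with `mode` (`"QBV"`) and
#'   `clauses`, each a sub-query with `feature`, `occurrence`, `terms`
#'   (data.frame term, boost) or `date_range`, optional `qualifiers`, and
#'   an `enrich` flag.
#' @export
parse_query <- function(text, schema = default_feature_schema()) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- "([+-]?)([A-Za-z]+)(@[A-Za-z,]+)?:\\(([^()]*)\\)"
  m <- gregexpr(pat, text)[[1]]

  if (m[1] == -1L) {
    toks <- tokenize(text)
    if (!length(toks)) stop("empty query")
    term_feats <- schema$feature[schema$kind == "term"]
    clauses <- lapply(term_feats, function(f) list(
      feature = f, occurrence = "SHOULD",
      terms = data.frame(term = toks, boost = 1, stringsAsFactors = FALSE),
      date_range = NULL, qualifiers = NULL, enrich = TRUE))
    return(structure(list(mode = "QBV", clauses = clauses),
                     class = "mrank_query"))
  }

  # all text outside clause matches must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(m))
    covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
  stray <- which(!covered &
                 !grepl("^\\s$", strsplit(text, "")[[1]], perl = TRUE))
  if (length(stray))
    stop("unexpected text at position ", stray[1], " in query: ", text)

  parts <- regmatches(text, list(m))[[1]]
  detail <- regmatches(parts, regexec(pat, parts))
  clauses <- list()
  seen <- character()
  for (j in seq_along(detail)) {
    d <- detail[[j]]
    pos <- m[j]
    occurrence <- switch(d[2], "+" = "MUST", "-" = "MUST_NOT", "SHOULD")
    fname <- d[3]
    if (tolower(fname) == "date") fname <- "creationDate"
    fi <- match(tolower(fname), tolower(schema$feature))
    if (is.na(fi))
      stop("unknown feature '", d[3], "' at position ", pos)
    feature <- schema$feature[fi]
    if (feature %in% seen)
      stop("duplicate feature '", feature, "' at position ", pos,
           " (query parts must be pairwise disjoint)")
    seen <- c(seen, feature)
    qualifiers <- NULL
    if (nzchar(d[4])) {
      qualifiers <- strsplit(sub("^@", "", d[4]), ",")[[1]]
      bad <- setdiff(qualifiers, miriam_qualifiers())
      if (length(bad))
        stop("unknown qualifier '", bad[1], "' at position ", pos)
    }
    payload <- trimws(d[5])
    if (schema$kind[fi] == "date") {
      dm <- regmatches(payload,
        regexec("^\\[\\s*(\\S+)\\s+-\\s+(\\S+)\\s*\\]$", payload))[[1]]
      if (length(dm) != 3L)
        stop("malformed date range at position ", pos, ": ", payload)
      rng <- as.Date(c(NA, NA))
      for (side in 1:2) {
        if (dm[side + 1] != "*") {
          rng[side] <- parse_flex_date(dm[side + 1])
          if (is.na(rng[side]))
            stop("unparseable date '", dm[side + 1], "' at position ", pos)
        }
      }
      clauses[[length(clauses) + 1L]] <- list(
        feature = feature, occurrence = occurrence, terms = NULL,
        date_range = rng, qualifiers = qualifiers, enrich = FALSE)
    } else {
      raw <- strsplit(payload, "\\s+")[[1]]
      raw <- raw[nzchar(raw)]
      if (!length(raw))
        stop("empty clause for feature '", feature, "' at position ", pos)
      tm <- regmatches(raw, regexec("^([^^]+)(\\^(.*))?$", raw))
      terms <- data.frame(term = character(), boost = numeric(),
                          stringsAsFactors = FALSE)
      for (t in tm) {
        boost <- 1
        if (length(t) >= 4L && nzchar(t[3])) {
          boost <- suppressWarnings(as.numeric(t[4]))
          if (is.na(boost) || boost <= 0)
            stop("malformed boost '", t[4], "' at position ", pos)
        }
        word <- tolower(t[2])
        if (!grepl("^[a-z0-9]+\\*?$", word))
          word <- paste(tokenize(word), collapse = "")
        if (!nzchar(sub("\\*$", "", word)))
          stop("empty term in feature '", feature, "' at position ", pos)
        terms <- rbind(terms, data.frame(term = word, boost = boost,
                                         stringsAsFactors = FALSE))
      }
      clauses[[length(clauses) + 1L]] <- list(
        feature = feature, occurrence = occurrence, terms = terms,
        date_range = NULL, qualifiers = qualifiers, enrich = TRUE)
    }
  }
  structure(list(mode = "QBV", clauses = clauses), class = "mrank_query")
}

#' @export
print.mrank_query <- function(x, ...) {
  cat("<mrank_query>", x$mode, "-", length(x$clauses), "clause(s)\n")
  invisible(x)
}

constituent_term_features <- function() {
  c("modelName", "species", "compartment", "reaction", "parameter",
    "event", "function")
}

#' Assemble a parsed query into the final engine query
#'
#' For every constituent term clause with enrichment on: (a) the clause
#' terms are resolved against the semantic index (honoring any qualifier
#' restriction) and a sibling URI clause is emitted on the corresponding
#' URI feature carrying the resolved URIs with their weights as boosts; a
#' MUST parent makes the sibling MUST in the same group, so the pair is
#' satisfied when either the literal terms or a resolved URI matches;
#' (b) each ontology expands the clause terms and the decayed expansion
#' tokens are appended as a SHOULD clause on the same feature. Original
#' clauses are always retained so literal term matches still count;
#' non-constituent clauses pass through unchanged.
#'
#' @param query an `mrank_query`.
#' @param sem optional `semantic_index`.
#' @param onts list of `ontology_graph` objects.
#' @param k top-k URIs taken from semantic resolution.
#' @param radius,decay ontology expansion range and per-edge weight decay.
#' @return an `assembled_query` with clause provenance labels
#'   (user/semantic/ontology).
#' @export
assemble <- function(query, sem = NULL, onts = list(), k = 10L,
                     radius = 2L, decay = 0.5) {
  stopifnot(inherits(query, "mrank_query"))
  clauses <- list()
  gid <- 0L
  for (sq in query$clauses) {
    gid <- gid + 1L
    if (!is.null(sq$date_range)) {
      clauses[[length(clauses) + 1L]] <- new_clause(
        sq$feature, sq$occurrence, "date", date_range = sq$date_range,
        provenance = "user", group = gid)
      next
    }
    clauses[[length(clauses) + 1L]] <- new_clause(
      sq$feature, sq$occurrence, "term", terms = sq$terms,
      provenance = "user", group = gid)
    enrichable <- isTRUE(sq$enrich) &&
      sq$feature %in% constituent_term_features()
    if (!enrichable) next
    plain <- sq$terms[!grepl("\\*$", sq$terms$term), , drop = FALSE]
    if (!nrow(plain)) next

    if (!is.null(sem)) {
      res <- resolve_terms(sem, plain$term, qualifier_filter = sq$qualifiers,
                           k = k)
      if (nrow(res)) {
        clauses[[length(clauses) + 1L]] <- new_clause(
          uri_feature_for(sq$feature),
          if (sq$occurrence == "MUST") "MUST" else "SHOULD",
          "uri", uris = data.frame(uri = res$uri, boost = res$weight,
                                   stringsAsFactors = FALSE),
          provenance = "semantic", group = gid)
      }
    }
    if (length(onts)) {
      exp_terms <- data.frame(term = character(), boost = numeric(),
                              stringsAsFactors = FALSE)
      for (ont in onts) for (i in seq_len(nrow(plain))) {
        ex <- expand_term(ont, plain$term[i], radius = radius, decay = decay)
        ex <- ex[ex$distance > 0, , drop = FALSE]
        for (r in seq_len(nrow(ex))) {
          toks <- tokenize(ex$term_text[r])
          toks <- setdiff(toks, sq$terms$term)
          if (length(toks))
            exp_terms <- rbind(exp_terms, data.frame(
              term = toks, boost = plain$boost[i] * ex$weight[r],
              stringsAsFactors = FALSE))
        }
      }
      if (nrow(exp_terms)) {
        # keep the strongest boost per expansion token
        exp_terms <- exp_terms[order(exp_terms$term, -exp_terms$boost), ,
                               drop = FALSE]
        exp_terms <- exp_terms[!duplicated(exp_terms$term), , drop = FALSE]
        rownames(exp_terms) <- NULL
        clauses[[length(clauses) + 1L]] <- new_clause(
          sq$feature, "SHOULD", "term", terms = exp_terms,
          provenance = "ontology", group = gid)
      }
    }
  }
  new_assembled_query(clauses)
}

#' Build a model search engine
#'
#' Parses and featurizes a corpus of SBML documents, builds the per-feature
#' model index and the semantic index, and bundles them with ontologies and
#' the weight configuration.
#'
#' @param models list of `annotated_model` objects, or a character vector of
#'   SBML file paths, or a directory containing `.xml`/`.sbml` files.
#' @param lexicon a `lexicon` (URI -> descriptive text) or NULL.
#' @param ontologies list of `ontology_graph` objects.
#' @param weights a `weight_config`.
#' @param schema a `feature_schema`.
#' @param k default number of URIs taken from semantic resolution.
#' @param radius,decay ontology expansion defaults.
#' @return object of class `model_search_engine`.
#' @export
build_engine <- function(models, lexicon = NULL, ontologies = list(),
                         weights = weight_config(),
                         schema = default_feature_schema(),
                         k = 10L, radius = 2L, decay = 0.5) {
  if (is.character(models)) {
    if (length(models) == 1L && dir.exists(models))
      models <- list.files(models, pattern = "\\.(xml|sbml)$",
                           full.names = TRUE)
    models <- lapply(models, parse_model)
  }
  reps <- lapply(models, featurize, schema = schema)
  if (is.null(lexicon)) lexicon <- as_lexicon(character(0))
  structure(list(
    index = build_model_index(reps),
    semantic = build_semantic_index(reps, lexicon),
    ontologies = ontologies, weights = weights, schema = schema,
    reps = reps, k = k, radius = radius, decay = decay),
    class = "model_search_engine")
}

#' @export
print.model_search_engine <- function(x, ...) {
  cat("<model_search_engine>", x$index$doc_count, "models,",
      x$semantic$doc_count, "semantic URIs,", length(x$ontologies),
      "ontology graph(s)\n")
  invisible(x)
}

#' Query by value
#'
#' Parses a query expression, assembles it (semantic + ontology enrichment
#' unless disabled), selects candidates with the extended-boolean algebra
#' and ranks them with the weighted vector-space scorer.
#'
#' @param engine a `model_search_engine`.
#' @param text query expression (see [parse_query()]).
#' @param enrich logical: expand constituent clauses through the semantic
#'   index and ontologies.
#' @param k top-k URIs per resolved clause.
#' @return a `scored_models` data.frame (may have zero rows).
#' @export
search_qbv <- function(engine, text, enrich = TRUE, k = engine$k) {
  stopifnot(inherits(engine, "model_search_engine"))
  q <- parse_query(text, engine$schema)
  if (!enrich)
    q$clauses <- lapply(q$clauses, function(cl) { cl$enrich <- FALSE; cl })
  aq <- assemble(q, sem = if (enrich) engine$semantic else NULL,
                 onts = if (enrich) engine$ontologies else list(),
                 k = k, radius = engine$radius, decay = engine$decay)
  cand <- retrieve_candidates(engine$index, aq)
  res <- rank_models(engine$index, cand, aq, engine$weights)
  attr(res, "query") <- aq
  res
}

#' Query by model example
#'
#' Featurizes an example model and searches for similar indexed models: one
#' SHOULD clause per non-empty term or URI feature (boosts 1; qualifier
#' weights still apply to URI matches). Enrichment is off — the example
#' itself provides the context.
#'
#' @param engine a `model_search_engine`.
#' @param example an `annotated_model`, or a path to an SBML file.
#' @return a `scored_models` data.frame.
#' @export
search_qbme <- function(engine, example) {
  stopifnot(inherits(engine, "model_search_engine"))
  if (is.character(example)) example <- parse_model(example)
  rep <- featurize(example, engine$schema)
  clauses <- list()
  for (f in names(rep$assignments)) {
    terms <- unique(rep$assignments[[f]])
    clauses[[length(clauses) + 1L]] <- new_clause(
      f, "SHOULD", "term",
      terms = data.frame(term = terms, boost = 1, stringsAsFactors = FALSE),
      provenance = "user")
  }
  for (f in names(rep$uri_assignments)) {
    uris <- unique(rep$uri_assignments[[f]]$uri)
    clauses[[length(clauses) + 1L]] <- new_clause(
      f, "SHOULD", "uri",
      uris = data.frame(uri = uris, boost = 1, stringsAsFactors = FALSE),
      provenance = "user")
  }
  if (!length(clauses)) stop("example model has no indexable features")
  aq <- new_assembled_query(clauses)
  cand <- retrieve_candidates(engine$index, aq)
  res <- rank_models(engine$index, cand, aq, engine$weights)
  attr(res, "query") <- aq
  res
}
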