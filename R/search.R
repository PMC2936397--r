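# A clause of an assembled query. type: "term" | "uri" | "date".
new_clause <- function(feature, occurrence, type, boost = 1,
                       terms = NULL, uris = NULL, date_range = NULL,
                       provenance = "user", group = NA_integer_) {
  stopifnot(occurrence %in% c("MUST", "SHOULD", "MUST_NOT"),
            type %in% c("term", "uri", "date"), boost > 0)
  structure(list(feature = feature, occurrence = occurrence, type = type,
                 boost = boost, terms = terms, uris = uris,
                 date_range = date_range, provenance = provenance,
                 group = group), class = "mrank_clause")
}

new_assembled_query <- function(clauses) {
  structure(list(clauses = clauses), class = "assembled_query")
}

#' @export
print.assembled_query <- function(x, ...) {
  pre <- c(MUST = "+", SHOULD = "", MUST_NOT = "-")
  for (cl in x$clauses) {
    payload <- switch(cl$type,
      term = paste0(cl$terms$term,
                    ifelse(cl$terms$boost != 1,
                           paste0("^", signif(cl$terms$boost, 3)), ""),
                    collapse = " "),
      uri = paste0(cl$uris$uri, "^", signif(cl$uris$boost, 3),
                   collapse = " "),
      date = paste0("[", ifelse(is.na(cl$date_range[1]), "*",
                                as.character(cl$date_range[1])),
                    " - ", ifelse(is.na(cl$date_range[2]), "*",
                                  as.character(cl$date_range[2])), "]"))
    cat(pre[[cl$occurrence]], cl$feature, ":(", payload, ")  <",
        cl$provenance, ">\n", sep = "")
  }
  invisible(x)
}

# expand wildcard terms (trailing *) against the indexed vocabulary of a
# feature; plain terms pass through
expand_clause_terms <- function(index, feature, terms_df) {
  wc <- grepl("\\*$", terms_df$term)
  if (!any(wc)) return(terms_df)
  vocab <- unique(index$terms$term[index$terms$feature == feature])
  out <- terms_df[!wc, , drop = FALSE]
  for (i in which(wc)) {
    prefix <- sub("\\*$", "", terms_df$term[i])
    hits <- vocab[startsWith(vocab, prefix)]
    if (length(hits))
      out <- rbind(out, data.frame(term = hits, boost = terms_df$boost[i],
                                   stringsAsFactors = FALSE))
  }
  out
}

# models matched by one clause (>= 1 term/URI present; date within range)
clause_matches <- function(index, clause) {
  if (clause$type == "term") {
    terms <- expand_clause_terms(index, clause$feature, clause$terms)
    hit <- index$terms$feature == clause$feature &
      index$terms$term %in% terms$term
    sort(unique(index$terms$model_id[hit]))
  } else if (clause$type == "uri") {
    hit <- index$uris$feature == clause$feature &
      index$uris$uri %in% clause$uris$uri
    sort(unique(index$uris$model_id[hit]))
  } else {
    d <- index$dates[index$dates$feature == clause$feature, , drop = FALSE]
    if (!nrow(d)) return(character())
    dd <- as.Date(d$date)
    ok <- rep(TRUE, nrow(d))
    if (!is.na(clause$date_range[1])) ok <- ok & dd >= clause$date_range[1]
    if (!is.na(clause$date_range[2])) ok <- ok & dd <= clause$date_range[2]
    sort(unique(d$model_id[ok]))
  }
}

#' Select candidate models with extended-boolean clause algebra
#'
#' A clause matches a model when at least one of its terms or URIs occurs
#' in the clause's feature field (dates: within range; wildcard terms:
#' prefix match). Candidates are the intersection of all MUST-clause match
#' sets minus the union of MUST_NOT match sets; with no MUST clause, the
#' union of SHOULD match sets minus MUST_NOT matches. MUST clauses sharing
#' a group (a literal clause and its semantically derived URI sibling) are
#' satisfied when either member matches.
#'
#' @param index a `model_index`.
#' @param query an `assembled_query` (see [assemble()]).
#' @return sorted character vector of candidate model ids.
#' @export
retrieve_candidates <- function(index, query) {
  stopifnot(inherits(index, "model_index"),
            inherits(query, "assembled_query"))
  occ <- vapply(query$clauses, `[[`, "", "occurrence")
  if (!any(occ %in% c("MUST", "SHOULD")))
    stop("unsatisfiable query: no MUST or SHOULD clause")
  matches <- lapply(query$clauses, clause_matches, index = index)

  must_i <- which(occ == "MUST")
  if (length(must_i)) {
    groups <- vapply(query$clauses[must_i], `[[`, NA_integer_, "group")
    groups[is.na(groups)] <- -seq_along(groups[is.na(groups)])
    cand <- NULL
    for (g in unique(groups)) {
      set <- sort(unique(unlist(matches[must_i[groups == g]],
                                use.names = FALSE)))
      cand <- if (is.null(cand)) set else intersect(cand, set)
    }
  } else {
    cand <- sort(unique(unlist(matches[occ == "SHOULD"], use.names = FALSE)))
  }
  not_set <- unique(unlist(matches[occ == "MUST_NOT"], use.names = FALSE))
  sort(setdiff(cand, not_set))
}

qualifier_weight_of <- function(weights, qualifier) {
  w <- weights$qualifier_weights[qualifier]
  w[is.na(w)] <- 1
  unname(w)
}

# score contribution of one clause for one candidate
clause_contribution <- function(index, clause, model_id, weights) {
  fw <- unname(weights$feature_weights[clause$feature])
  if (is.na(fw)) fw <- 1
  if (clause$type == "term") {
    terms <- expand_clause_terms(index, clause$feature, clause$terms)
    if (!nrow(terms)) return(0)
    nrm <- field_norm(index, model_id, clause$feature)
    if (nrm == 0) return(0)
    s <- 0
    for (i in seq_len(nrow(terms))) {
      cnt <- index$terms$count[index$terms$model_id == model_id &
                               index$terms$feature == clause$feature &
                               index$terms$term == terms$term[i]]
      if (length(cnt))
        s <- s + terms$boost[i] * sqrt(cnt[1]) *
          index_idf(index, clause$feature, terms$term[i])
    }
    fw * clause$boost * s / nrm
  } else if (clause$type == "uri") {
    s <- 0
    for (i in seq_len(nrow(clause$uris))) {
      quals <- index$uris$qualifier[index$uris$model_id == model_id &
                                    index$uris$feature == clause$feature &
                                    index$uris$uri == clause$uris$uri[i]]
      if (length(quals))
        s <- s + clause$uris$boost[i] *
          max(qualifier_weight_of(weights, quals))
    }
    fw * clause$boost * s
  } else {
    matched <- model_id %in% clause_matches(index, clause)
    if (matched) fw * clause$boost else 0
  }
}

clause_label <- function(clause, i) {
  pre <- c(MUST = "+", SHOULD = "", MUST_NOT = "-")
  paste0("[", i, "] ", pre[[clause$occurrence]], clause$feature,
         "/", clause$type, " <", clause$provenance, ">")
}

#' Rank candidate models with the weighted vector-space scorer
#'
#' `score(c) = sum over non-MUST_NOT clauses s of W(f) * B_s * sim_s(c)`,
#' where for term clauses `sim` is the boost-weighted sum of tf-idf term
#' weights divided by the model's field norm, for URI clauses the
#' boost-weighted sum of the best qualifier weight linking each URI
#' (document-side normalization deliberately omitted: an exact URI hit must
#' not be penalized when a model annotates many elements), and date clauses
#' contribute 1 when the model's date falls in range. Sorted by descending
#' score, ties by ascending model id.
#'
#' @param index a `model_index`.
#' @param candidates character vector of model ids (subset of the index).
#' @param query an `assembled_query`.
#' @param weights a `weight_config`.
#' @return object of class `scored_models`: data.frame with `model_id` and
#'   `score`, with per-clause contribution tables in
#'   `attr(, "explanations")` (named by model id).
#' @export
rank_models <- function(index, candidates, query, weights = weight_config()) {
  stopifnot(inherits(index, "model_index"),
            inherits(query, "assembled_query"),
            inherits(weights, "weight_config"),
            all(candidates %in% index$model_ids))
  scored <- vapply(candidates, function(m) 0, 0)
  explanations <- stats::setNames(vector("list", length(candidates)),
                                  candidates)
  keep <- which(vapply(query$clauses, `[[`, "", "occurrence") != "MUST_NOT")
  for (m in candidates) {
    contrib <- vapply(keep, function(i)
      clause_contribution(index, query$clauses[[i]], m, weights), 0)
    explanations[[m]] <- data.frame(
      clause = vapply(keep, function(i) clause_label(query$clauses[[i]], i), ""),
      contribution = contrib, stringsAsFactors = FALSE)
    scored[[m]] <- sum(contrib)
  }
  ord <- order(-scored, candidates)
  out <- data.frame(model_id = candidates[ord], score = unname(scored[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "explanations") <- explanations
  class(out) <- c("scored_models", "data.frame")
  out
}

#' @export
print.scored_models <- function(x, ...) {
  cat("<scored_models>", nrow(x), "hit(s)\n")
  if (nrow(x))
    print(data.frame(rank = seq_len(nrow(x)), model_id = x$model_id,
                     score = signif(x$score, 6)), row.names = FALSE)
  invisible(x)
}

#' Per-clause score explanation for one ranked model
#'
#' @param results a `scored_models` object from [rank_models()].
#' @param model_id which hit to explain; defaults to the top-ranked model.
#' @return character scalar: a human-readable contribution table whose
#'   lines sum to the model's score (also printed).
#' @export
explain <- function(results, model_id = NULL) {
  stopifnot(inherits(results, "scored_models"), nrow(results) >= 1)
  if (is.null(model_id)) model_id <- results$model_id[1]
  ex <- attr(results, "explanations")[[model_id]]
  if (is.null(ex)) stop("no explanation for model ", model_id)
  score <- results$score[results$model_id == model_id]
  lines <- c(paste0("model ", model_id, "  score ", format(score)),
             sprintf("  %-48s %+.6f", ex$clause, ex$contribution),
             sprintf("  %-48s %+.6f", "total", sum(ex$contribution)))
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}
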