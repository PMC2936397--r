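# Independent brute-force scorer working directly on raw representations:
# recomputes tf, idf, field norms, clause matching and clause sums without
# touching the model_index internals.

bf_df <- function(reps, feature, term) {
  sum(vapply(reps, function(r) term %in% r$assignments[[feature]], logical(1)))
}

bf_idf <- function(reps, feature, term)
  1 + log(length(reps) / (1 + bf_df(reps, feature, term)))

bf_tw <- function(reps, rep, feature, term) {
  cnt <- sum(rep$assignments[[feature]] == term)
  if (cnt == 0) return(0)
  sqrt(cnt) * bf_idf(reps, feature, term)
}

bf_norm <- function(reps, rep, feature) {
  toks <- rep$assignments[[feature]]
  if (is.null(toks) || !length(toks)) return(0)
  sqrt(sum(vapply(unique(toks), function(t)
    bf_tw(reps, rep, feature, t)^2, 0)))
}

bf_terms_of_clause <- function(reps, clause) {
  wc <- grepl("\\*$", clause$terms$term)
  out <- clause$terms[!wc, , drop = FALSE]
  if (any(wc)) {
    vocab <- unique(unlist(lapply(reps, function(r)
      r$assignments[[clause$feature]]), use.names = FALSE))
    for (i in which(wc)) {
      hits <- vocab[startsWith(vocab, sub("\\*$", "", clause$terms$term[i]))]
      if (length(hits))
        out <- rbind(out, data.frame(term = hits,
                                     boost = clause$terms$boost[i]))
    }
  }
  out
}

bf_matches <- function(reps, clause) {
  hit <- vapply(reps, function(r) {
    if (clause$type == "term") {
      terms <- bf_terms_of_clause(reps, clause)
      any(terms$term %in% r$assignments[[clause$feature]])
    } else if (clause$type == "uri") {
      ua <- r$uri_assignments[[clause$feature]]
      !is.null(ua) && any(clause$uris$uri %in% ua$uri)
    } else {
      d <- r$dates[[clause$feature]]
      !is.null(d) &&
        (is.na(clause$date_range[1]) || d >= clause$date_range[1]) &&
        (is.na(clause$date_range[2]) || d <= clause$date_range[2])
    }
  }, logical(1))
  vapply(reps, `[[`, "", "model_id")[hit]
}

bf_candidates <- function(reps, aq) {
  occ <- vapply(aq$clauses, `[[`, "", "occurrence")
  matches <- lapply(aq$clauses, bf_matches, reps = reps)
  must_i <- which(occ == "MUST")
  if (length(must_i)) {
    groups <- vapply(aq$clauses[must_i], `[[`, NA_integer_, "group")
    groups[is.na(groups)] <- -seq_along(groups[is.na(groups)])
    cand <- NULL
    for (g in unique(groups)) {
      set <- unique(unlist(matches[must_i[groups == g]]))
      cand <- if (is.null(cand)) set else intersect(cand, set)
    }
  } else {
    cand <- unique(unlist(matches[occ == "SHOULD"]))
  }
  sort(setdiff(cand, unlist(matches[occ == "MUST_NOT"])))
}

bf_score <- function(reps, rep, aq, weights) {
  total <- 0
  for (clause in aq$clauses) {
    if (clause$occurrence == "MUST_NOT") next
    fw <- unname(weights$feature_weights[clause$feature])
    if (is.na(fw)) fw <- 1
    if (clause$type == "term") {
      nrm <- bf_norm(reps, rep, clause$feature)
      if (nrm == 0) next
      terms <- bf_terms_of_clause(reps, clause)
      s <- sum(vapply(seq_len(nrow(terms)), function(i)
        terms$boost[i] * bf_tw(reps, rep, clause$feature, terms$term[i]), 0))
      total <- total + fw * clause$boost * s / nrm
    } else if (clause$type == "uri") {
      ua <- rep$uri_assignments[[clause$feature]]
      if (is.null(ua)) next
      s <- 0
      for (i in seq_len(nrow(clause$uris))) {
        quals <- ua$qualifier[ua$uri == clause$uris$uri[i]]
        if (length(quals)) {
          qs <- weights$qualifier_weights[quals]
          qs[is.na(qs)] <- 1
          s <- s + clause$uris$boost[i] * max(qs)
        }
      }
      total <- total + fw * clause$boost * s
    } else {
      if (rep$model_id %in% bf_matches(reps, clause))
        total <- total + fw * clause$boost
    }
  }
  total
}

bf_rank <- function(reps, candidates, aq, weights) {
  byid <- stats::setNames(reps, vapply(reps, `[[`, "", "model_id"))
  scores <- vapply(candidates, function(m)
    bf_score(reps, byid[[m]], aq, weights), 0)
  ord <- order(-scores, candidates)
  data.frame(model_id = candidates[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}

# Random assembled query over a corpus' own vocabulary (plus some misses).
random_query <- function(reps, max_clauses = 5) {
  feats <- unique(unlist(lapply(reps, function(r) names(r$assignments))))
  ufeats <- unique(unlist(lapply(reps, function(r) names(r$uri_assignments))))
  n_clause <- sample.int(max_clauses, 1)
  clauses <- list()
  for (i in seq_len(n_clause)) {
    occurrence <- sample(c("MUST", "SHOULD", "SHOULD", "MUST_NOT"), 1)
    kind <- sample(c("term", "term", "uri", "date"), 1)
    if (kind == "uri" && length(ufeats)) {
      f <- sample(ufeats, 1)
      uris <- unique(unlist(lapply(reps, function(r)
        r$uri_assignments[[f]]$uri)))
      pick <- sample(uris, min(length(uris), sample.int(3, 1)))
      clauses[[length(clauses) + 1L]] <- mrank:::new_clause(
        f, occurrence, "uri",
        uris = data.frame(uri = pick, boost = round(stats::runif(length(pick),
                                                                 0.2, 1), 3),
                          stringsAsFactors = FALSE))
    } else if (kind == "date") {
      f <- sample(c("creationDate", "modificationDate"), 1)
      clauses[[length(clauses) + 1L]] <- mrank:::new_clause(
        f, occurrence, "date",
        date_range = as.Date(c("2005-06-01", "2010-06-01")))
    } else {
      f <- sample(feats, 1)
      vocab <- unique(unlist(lapply(reps, function(r) r$assignments[[f]])))
      pick <- c(sample(vocab, min(length(vocab), sample.int(3, 1))),
                if (stats::runif(1) < 0.3) "zyzzyva")
      if (stats::runif(1) < 0.3 && nchar(pick[1]) > 2)
        pick[1] <- paste0(substr(pick[1], 1, 3), "*")
      clauses[[length(clauses) + 1L]] <- mrank:::new_clause(
        f, occurrence, "term",
        terms = data.frame(term = pick,
                           boost = round(stats::runif(length(pick), 0.5, 3), 3),
                           stringsAsFactors = FALSE))
    }
  }
  occ <- vapply(clauses, `[[`, "", "occurrence")
  if (!any(occ %in% c("MUST", "SHOULD")))
    clauses[[1]]$occurrence <- "SHOULD"
  mrank:::new_assembled_query(clauses)
}
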