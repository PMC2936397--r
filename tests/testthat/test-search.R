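toy_reps <- function() {
  list(
    make_rep("t1", assignments = list(species = c("caffeine", "atp"),
                                      author = c("john", "doe")),
             dates = list(creationDate = as.Date("2009-05-01"))),
    make_rep("t2", assignments = list(species = "caffeine",
                                      author = c("anna", "keller")),
             dates = list(creationDate = as.Date("2007-05-01"))),
    make_rep("t3", assignments = list(species = "glucose",
                                      author = c("anna", "keller")),
             uri_assignments = list(speciesURI = "urn:miriam:obo.chebi:CHEBI%3A17234"),
             dates = list(creationDate = as.Date("2009-08-01"))),
    make_rep("t4", assignments = list(species = c("glucose", "atp"),
                                      author = c("emil", "novak"))))
}

tq <- function(feature, occurrence, terms, boosts = 1, group = NA_integer_)
  mrank:::new_clause(feature, occurrence, "term",
                     terms = data.frame(term = terms, boost = boosts,
                                        stringsAsFactors = FALSE),
                     group = group)

test_that("candidate selection follows MUST/SHOULD/MUST_NOT set algebra", {
  idx <- build_model_index(toy_reps())
  aq <- mrank:::new_assembled_query(list(
    tq("species", "MUST", "caffeine"),
    tq("species", "SHOULD", "atp"),
    tq("author", "MUST_NOT", c("john", "doe"))))
  cand <- retrieve_candidates(idx, aq)
  expect_identical(cand, "t2")                      # t1 excluded by MUST_NOT
  expect_identical(cand, bf_candidates(toy_reps(), aq))
  # no MUST: union of SHOULD minus MUST_NOT
  aq2 <- mrank:::new_assembled_query(list(
    tq("species", "SHOULD", c("atp", "glucose")),
    tq("author", "MUST_NOT", "novak")))
  expect_identical(retrieve_candidates(idx, aq2), c("t1", "t3"))
  expect_identical(retrieve_candidates(idx, aq2),
                   bf_candidates(toy_reps(), aq2))
  # MUST on an absent term
  aq3 <- mrank:::new_assembled_query(list(tq("species", "MUST", "zyzzyva")))
  expect_identical(retrieve_candidates(idx, aq3), character())
  # only MUST_NOT clauses: unsatisfiable
  expect_error(retrieve_candidates(idx, mrank:::new_assembled_query(
    list(tq("species", "MUST_NOT", "atp")))), "unsatisfiable")
})

test_that("grouped MUST clauses (literal OR derived URI) are satisfied by either member", {
  idx <- build_model_index(toy_reps())
  aq <- mrank:::new_assembled_query(list(
    tq("species", "MUST", "glucose", group = 1L),
    mrank:::new_clause("speciesURI", "MUST", "uri",
                       uris = data.frame(uri = "urn:miriam:obo.chebi:CHEBI%3A17234",
                                         boost = 1, stringsAsFactors = FALSE),
                       group = 1L)))
  expect_identical(retrieve_candidates(idx, aq), c("t3", "t4"))
})

test_that("wildcard terms match by prefix and date clauses by range", {
  idx <- build_model_index(toy_reps())
  aq <- mrank:::new_assembled_query(list(tq("species", "MUST", "caf*")))
  expect_identical(retrieve_candidates(idx, aq), c("t1", "t2"))
  aqd <- mrank:::new_assembled_query(list(mrank:::new_clause(
    "creationDate", "MUST", "date",
    date_range = c(as.Date("2009-01-01"), as.Date(NA)))))
  expect_identical(retrieve_candidates(idx, aqd), c("t1", "t3"))
})

test_that("an is-linked model outranks an otherwise identical isDescribedBy-linked model", {
  uri <- "urn:miriam:obo.chebi:CHEBI%3A27732"
  mk <- function(id, qual) make_rep(id,
    assignments = list(species = "caffeine"),
    uri_assignments = list(speciesURI = data.frame(
      uri = uri, qualifier = qual, prefix = "bqbiol",
      stringsAsFactors = FALSE)))
  reps <- list(mk("m_is", "is"), mk("m_idb", "isDescribedBy"))
  idx <- build_model_index(reps)
  aq <- mrank:::new_assembled_query(list(mrank:::new_clause(
    "speciesURI", "SHOULD", "uri",
    uris = data.frame(uri = uri, boost = 1, stringsAsFactors = FALSE))))
  res <- rank_models(idx, retrieve_candidates(idx, aq), aq)
  expect_identical(res$model_id, c("m_is", "m_idb"))
  expect_gt(res$score[1], res$score[2])
  expect_equal(res$score[1] / res$score[2], 2.0 / 1.0, tolerance = 1e-9)
})

test_that("byte-identical models tie; the best qualifier linking a URI wins", {
  uri <- "urn:miriam:obo.chebi:CHEBI%3A27732"
  mk <- function(id) make_rep(id,
    assignments = list(species = "caffeine"),
    uri_assignments = list(speciesURI = data.frame(
      uri = c(uri, uri), qualifier = c("isDescribedBy", "is"),
      prefix = "bqbiol", stringsAsFactors = FALSE)))
  reps <- list(mk("dup1"), mk("dup2"))
  idx <- build_model_index(reps)
  aq <- mrank:::new_assembled_query(list(mrank:::new_clause(
    "speciesURI", "SHOULD", "uri",
    uris = data.frame(uri = uri, boost = 0.5, stringsAsFactors = FALSE))))
  res <- rank_models(idx, c("dup1", "dup2"), aq)
  expect_equal(res$score[1], res$score[2], tolerance = 1e-12)
  expect_identical(res$model_id, c("dup1", "dup2"))  # tie -> ascending id
  # best qualifier (is, 2.0) applies: W(speciesURI)=5 * 0.5 * 2.0
  expect_equal(res$score[1], 5 * 0.5 * 2.0, tolerance = 1e-9)
})

test_that("scores match the brute-force oracle on seeded corpora and queries", {
  set.seed(99)
  w <- weight_config()
  for (trial in 1:12) {
    reps <- corpus_reps(sample(3:8, 1), seed = 100 + trial)
    idx <- build_model_index(reps)
    aq <- random_query(reps)
    cand <- retrieve_candidates(idx, aq)
    expect_identical(cand, bf_candidates(reps, aq))
    if (!length(cand)) next
    res <- rank_models(idx, cand, aq, w)
    bf <- bf_rank(reps, cand, aq, w)
    expect_identical(res$model_id, bf$model_id)
    expect_equal(res$score, bf$score, tolerance = 1e-9)
  }
})

test_that("raising a clause boost never demotes matching models below non-matching ones", {
  reps <- toy_reps()
  idx <- build_model_index(reps)
  base <- list(tq("species", "SHOULD", "caffeine"),
               tq("species", "SHOULD", "glucose"))
  cand <- retrieve_candidates(idx, mrank:::new_assembled_query(base))
  matching <- c("t1", "t2")  # models matching the caffeine clause
  for (b in c(1, 2, 5, 20)) {
    boosted <- base
    boosted[[1]]$boost <- b
    res <- rank_models(idx, cand, mrank:::new_assembled_query(boosted))
    worst_match <- max(match(matching, res$model_id))
    best_nonmatch <- min(match(setdiff(cand, matching), res$model_id))
    if (b >= 5) expect_lt(worst_match, best_nonmatch)
    expect_true(all(res$score >= 0))
  }
})

test_that("MUST_NOT exclusion is complete on random corpora", {
  set.seed(7)
  for (trial in 1:5) {
    reps <- corpus_reps(6, seed = 300 + trial)
    idx <- build_model_index(reps)
    aq <- random_query(reps)
    cand <- retrieve_candidates(idx, aq)
    for (clause in aq$clauses)
      if (clause$occurrence == "MUST_NOT")
        expect_length(intersect(cand, bf_matches(reps, clause)), 0L)
  }
})

test_that("explanations are per-clause and sum to the score", {
  reps <- toy_reps()
  idx <- build_model_index(reps)
  aq <- mrank:::new_assembled_query(list(
    tq("species", "MUST", c("caffeine", "atp"), boosts = c(2, 1)),
    mrank:::new_clause("creationDate", "SHOULD", "date",
                       date_range = c(as.Date("2009-01-01"), as.Date(NA))),
    tq("author", "MUST_NOT", "novak")))
  res <- rank_models(idx, retrieve_candidates(idx, aq), aq)
  for (m in res$model_id) {
    ex <- attr(res, "explanations")[[m]]
    expect_equal(sum(ex$contribution), res$score[res$model_id == m],
                 tolerance = 1e-9)
    expect_false(any(grepl("MUST_NOT|-author", ex$clause)))
  }
  txt <- explain(res, res$model_id[1])
  expect_match(txt, "creationDate/date")
  # date clause contributes W(creationDate) * B = 1 for matching models
  ex1 <- attr(res, "explanations")[["t1"]]
  expect_equal(ex1$contribution[grepl("date", ex1$clause)], 1,
               tolerance = 1e-12)
  # single clause: the one contribution equals the score
  aq1 <- mrank:::new_assembled_query(list(tq("species", "SHOULD", "glucose")))
  res1 <- rank_models(idx, retrieve_candidates(idx, aq1), aq1)
  ex <- attr(res1, "explanations")[[res1$model_id[1]]]
  expect_identical(nrow(ex), 1L)
  expect_equal(ex$contribution, res1$score[1], tolerance = 1e-12)
})
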