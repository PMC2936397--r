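#' Build the per-feature inverted model index
#'
#' Indexes a featurized corpus: term postings with counts per (feature,
#' term, model), URI postings with qualifier sets, per-(model, feature)
#' Euclidean norms of the tf-idf vectors, and day-precision dates.
#'
#' @param reps list of `model_representation` objects with unique model ids.
#' @return object of class `model_index`.
#' @export
build_model_index <- function(reps) {
  ids <- vapply(reps, `[[`, "", "model_id")
  if (anyDuplicated(ids))
    stop("duplicate model_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  tl <- list()
  ul <- list()
  dl <- list()
  for (rep in reps) {
    stopifnot(inherits(rep, "model_representation"))
    for (f in names(rep$assignments)) {
      cnt <- table(rep$assignments[[f]])
      tl[[length(tl) + 1L]] <- data.frame(
        model_id = rep$model_id, feature = f, term = names(cnt),
        count = as.integer(cnt), stringsAsFactors = FALSE)
    }
    for (f in names(rep$uri_assignments)) {
      ua <- unique(rep$uri_assignments[[f]][, c("uri", "qualifier")])
      ul[[length(ul) + 1L]] <- data.frame(
        model_id = rep$model_id, feature = f, uri = ua$uri,
        qualifier = ua$qualifier, stringsAsFactors = FALSE)
    }
    for (f in names(rep$dates))
      dl[[length(dl) + 1L]] <- data.frame(
        model_id = rep$model_id, feature = f,
        date = as.character(rep$dates[[f]]), stringsAsFactors = FALSE)
  }
  bind <- function(lst, proto) {
    if (!length(lst)) return(proto)
    out <- do.call(rbind, lst)
    out <- out[do.call(order, out), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  terms <- bind(tl, data.frame(model_id = character(), feature = character(),
                               term = character(), count = integer(),
                               stringsAsFactors = FALSE))
  uris <- bind(ul, data.frame(model_id = character(), feature = character(),
                              uri = character(), qualifier = character(),
                              stringsAsFactors = FALSE))
  dates <- bind(dl, data.frame(model_id = character(), feature = character(),
                               date = character(), stringsAsFactors = FALSE))

  idx <- structure(list(model_ids = sort(ids), doc_count = length(ids),
                        terms = terms, uris = uris, dates = dates,
                        df = NULL, norms = NULL),
                   class = "model_index")
  idx$df <- compute_df(terms)
  idx$norms <- compute_norms(idx)
  idx
}

# document frequency per (feature, term): number of models whose field
# contains the term
compute_df <- function(terms) {
  if (!nrow(terms))
    return(data.frame(feature = character(), term = character(),
                      df = integer(), stringsAsFactors = FALSE))
  key <- paste(terms$feature, terms$term, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(feature = vapply(parts, `[[`, "", 1L),
                    term = vapply(parts, `[[`, "", 2L),
                    df = as.integer(tab), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

index_idf <- function(index, feature, term) {
  hit <- index$df$df[index$df$feature == feature & index$df$term == term]
  d <- if (length(hit)) hit[1] else 0L
  1 + log(index$doc_count / (1 + d))
}

compute_norms <- function(index) {
  t <- index$terms
  if (!nrow(t))
    return(data.frame(model_id = character(), feature = character(),
                      norm = numeric(), stringsAsFactors = FALSE))
  dfs <- index$df$df[match(paste(t$feature, t$term, sep = "\r"),
                           paste(index$df$feature, index$df$term, sep = "\r"))]
  w <- sqrt(t$count) * (1 + log(index$doc_count / (1 + dfs)))
  key <- paste(t$model_id, t$feature, sep = "\r")
  agg <- tapply(w^2, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(model_id = vapply(parts, `[[`, "", 1L),
                    feature = vapply(parts, `[[`, "", 2L),
                    norm = sqrt(as.numeric(agg)), stringsAsFactors = FALSE)
  out <- out[order(out$model_id, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.model_index <- function(x, ...) {
  cat("<model_index>", x$doc_count, "models,", nrow(x$terms),
      "term postings,", nrow(x$uris), "URI postings\n")
  invisible(x)
}

#' tf-idf weight of a term in a model's feature field
#'
#' `tf = sqrt(count)` of the term in the model's field;
#' `idf = 1 + ln(doc_count / (1 + df))` with `df` the number of models whose
#' field contains the term. Returns 0 when the term is absent from the
#' model's field.
#'
#' @param index a `model_index`.
#' @param feature feature name.
#' @param term a single lowercase token.
#' @param model_id an indexed model id (unknown ids are an error).
#' @return non-negative numeric weight.
#' @export
term_weight <- function(index, feature, term, model_id) {
  stopifnot(inherits(index, "model_index"))
  if (!model_id %in% index$model_ids)
    stop("unknown model_id: ", model_id)
  cnt <- index$terms$count[index$terms$model_id == model_id &
                           index$terms$feature == feature &
                           index$terms$term == term]
  if (!length(cnt)) return(0)
  sqrt(cnt[1]) * index_idf(index, feature, term)
}

field_norm <- function(index, model_id, feature) {
  hit <- index$norms$norm[index$norms$model_id == model_id &
                          index$norms$feature == feature]
  if (length(hit)) hit[1] else 0
}

#' Serialize a model index to JSON
#'
#' Postings and dates are written; document frequencies and field norms are
#' recomputed deterministically on load, so a written-and-reread index is
#' identical to the original.
#' @param index a `model_index`.
#' @param path output file path.
#' @export
write_model_index <- function(index, path) {
  stopifnot(inherits(index, "model_index"))
  jsonlite::write_json(
    list(model_ids = index$model_ids, terms = index$terms,
         uris = index$uris, dates = index$dates),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a model index written by [write_model_index()]
#' @param path JSON file path.
#' @return a `model_index`.
#' @export
read_model_index <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(df, proto) {
    if (is.null(df) || !length(df) || !NROW(df)) return(proto)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if ("count" %in% names(df)) df$count <- as.integer(df$count)
    df
  }
  idx <- structure(list(
    model_ids = as.character(raw$model_ids),
    doc_count = length(raw$model_ids),
    terms = fix(raw$terms, data.frame(model_id = character(),
                                      feature = character(),
                                      term = character(), count = integer(),
                                      stringsAsFactors = FALSE)),
    uris = fix(raw$uris, data.frame(model_id = character(),
                                    feature = character(), uri = character(),
                                    qualifier = character(),
                                    stringsAsFactors = FALSE)),
    dates = fix(raw$dates, data.frame(model_id = character(),
                                      feature = character(),
                                      date = character(),
                                      stringsAsFactors = FALSE)),
    df = NULL, norms = NULL), class = "model_index")
  idx$df <- compute_df(idx$terms)
  idx$norms <- compute_norms(idx)
  idx
}
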