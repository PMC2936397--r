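#' Load an OBO 1.2 flat-file ontology
#'
#' Parses `[Term]` stanzas into a directed labeled graph. Recognised tag
#' lines per stanza: `id`, `name`, `synonym` (quoted text), `is_a`,
#' `relationship: part_of <id>` (other relationship types are kept with
#' their own label), `is_obsolete`. Obsolete terms are excluded; edges to
#' excluded or unknown terms are dropped.
#'
#' @param path path to an OBO file.
#' @return object of class `ontology_graph`: list with `graph` (an igraph
#'   with vertex attributes `name` = term_id, `term_name`, `synonyms` (list)
#'   and edge attribute `label`) and `terms` (data.frame term_id, name).
#' @export
load_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  start_line <- 0L
  flush <- function(cur, at) {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id))
      stop("OBO [Term] stanza starting at line ", at, " has no id", call. = FALSE)
    if (!isTRUE(cur$obsolete)) terms[[cur$id]] <<- cur
    invisible()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "!")) next
    if (grepl("^\\[", ln)) {
      flush(cur, start_line)
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = "", synonyms = character(),
                    edges = list(), obsolete = FALSE)
        start_line <- i
      }
      next
    }
    if (!in_term) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("unparseable OBO line ", i, ": ", ln, call. = FALSE)
    tag <- m[2]
    val <- sub("\\s*!.*$", "", m[3])
    if (tag == "id") cur$id <- trimws(val)
    else if (tag == "name") cur$name <- trimws(val)
    else if (tag == "synonym") {
      sm <- regmatches(val, regexec("^\"([^\"]*)\"", val))[[1]]
      if (length(sm) != 2L)
        stop("unparseable synonym at OBO line ", i, ": ", ln, call. = FALSE)
      cur$synonyms <- c(cur$synonyms, sm[2])
    } else if (tag == "is_a") {
      cur$edges[[length(cur$edges) + 1L]] <- c("is_a", trimws(val))
    } else if (tag == "relationship") {
      rm_ <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(rm_) < 2L)
        stop("unparseable relationship at OBO line ", i, ": ", ln, call. = FALSE)
      cur$edges[[length(cur$edges) + 1L]] <- c(rm_[1], rm_[2])
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(trimws(val), "true")
    }
  }
  flush(cur, start_line)

  ids <- names(terms)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
    term_name = vapply(terms, `[[`, "", "name"))
  g <- igraph::set_vertex_attr(g, "synonyms",
    value = lapply(terms, `[[`, "synonyms"))
  edges <- character()
  labels <- character()
  for (tm in terms) for (e in tm$edges) {
    if (e[2] %in% ids) {
      edges <- c(edges, tm$id, e[2])
      labels <- c(labels, e[1])
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges, label = labels)
  structure(list(graph = g,
                 terms = data.frame(term_id = ids,
                                    name = vapply(terms, `[[`, "", "name"),
                                    stringsAsFactors = FALSE,
                                    row.names = NULL)),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph>", igraph::vcount(x$graph), "terms,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Expand a term through an ontology
#'
#' Finds ontology terms whose name or any synonym matches the query term
#' (case-insensitive exact match) and returns every term within undirected
#' graph distance `radius` of a match, weighted `decay^distance`. Edge
#' labels (is_a, part_of, ...) are treated equally for distance. Both names
#' and synonyms of reached terms are emitted, lowercased.
#'
#' @param ont an `ontology_graph`.
#' @param term query term text (single string; matching ignores case).
#' @param radius maximum undirected distance (>= 0).
#' @param decay multiplicative weight decay per edge, in (0, 1).
#' @return data.frame with columns `term_text`, `weight` (in (0,1];
#'   `decay^distance`), `distance` and `origin` (term_id of the reached
#'   node). Empty when the term matches no node. The seed term's own node
#'   appears at distance 0 with weight 1. Sorted by distance, then term.
#' @export
expand_term <- function(ont, term, radius = 2L, decay = 0.5) {
  stopifnot(inherits(ont, "ontology_graph"), radius >= 0,
            decay > 0, decay < 1)
  g <- ont$graph
  empty <- data.frame(term_text = character(), weight = numeric(),
                      distance = integer(), origin = character(),
                      stringsAsFactors = FALSE)
  if (igraph::vcount(g) == 0L) return(empty)
  needle <- tolower(trimws(term))
  nm <- tolower(igraph::vertex_attr(g, "term_name"))
  syn <- igraph::vertex_attr(g, "synonyms")
  seed <- which(nm == needle |
                vapply(syn, function(s) needle %in% tolower(s), logical(1)))
  if (!length(seed)) return(empty)
  d <- igraph::distances(g, v = seed, mode = "all")
  mind <- apply(d, 2, min)
  reach <- which(is.finite(mind) & mind <= radius)
  rows <- list()
  for (v in reach) {
    dist <- as.integer(mind[v])
    texts <- unique(tolower(c(igraph::vertex_attr(g, "term_name")[v],
                              unlist(syn[v], use.names = FALSE))))
    texts <- texts[nzchar(texts)]
    for (tx in texts)
      rows[[length(rows) + 1L]] <- data.frame(
        term_text = tx, weight = decay^dist, distance = dist,
        origin = igraph::vertex_attr(g, "name")[v], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$distance, out$term_text, out$origin), , drop = FALSE]
  rownames(out) <- NULL
  out
}
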