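#' Tokenize free text into lowercase index tokens
#'
#' Splits on any character that is neither an ASCII letter nor a digit and
#' lowercases the result. Single-character tokens are kept, so chemical
#' formulas rendered as one run of letters and digits (e.g. "c8h10n4o2")
#' survive as a single token. Deterministic: identical input bytes always
#' produce identical token vectors.
#'
#' @param x character vector of raw text (NA and empty strings allowed).
#' @return character vector of lowercase tokens (possibly empty), duplicates
#'   retained in input order.
#' @examples
#' tokenize("1,3,7-Trimethylxanthine (caffeine)")
#' @export
tokenize <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(character())
  toks <- unlist(strsplit(tolower(x), "[^a-z0-9]+"), use.names = FALSE)
  toks[nzchar(toks)]
}

#' BioModels.net annotation qualifiers
#'
#' The recognised qualifier names, shared between the `bqbiol` (biology)
#' and `bqmodel` (model) vocabularies.
#' @return character vector of the 13 qualifier names.
#' @export
miriam_qualifiers <- function() {
  c("is", "isHomologTo", "hasPart", "isPartOf", "isVersionOf", "hasVersion",
    "isEncodedBy", "isDerivedFrom", "encodes", "isDescribedBy", "occursIn",
    "hasProperty", "isPropertyOf")
}

# percent-decode an identifier; tolerant of malformed escapes
percent_decode <- function(x) {
  vapply(x, function(s) {
    out <- tryCatch(utils::URLdecode(s), error = function(e) s)
    out
  }, character(1), USE.NAMES = FALSE)
}

# canonical re-encoding for storage: only ":" is escaped (as in MIRIAM URNs,
# where identifiers like CHEBI:27732 print as CHEBI%3A27732)
percent_encode_id <- function(x) {
  gsub("%", "%25", x, fixed = TRUE) -> x
  gsub(":", "%3A", x, fixed = TRUE)
}

#' Normalize a MIRIAM URN
#'
#' Canonicalizes a `urn:miriam:<namespace>:<identifier>` URN: the scheme and
#' namespace are lowercased, percent-escapes in the identifier are decoded
#' (case preserved) and the identifier is re-encoded with `":"` as `"%3A"`.
#' Normalization is idempotent.
#'
#' @param uri character vector of URNs.
#' @return data.frame with columns `uri` (normalized text), `data_type`
#'   (namespace), `identifier` (decoded), and logical `valid`. Invalid URNs
#'   get `valid = FALSE` and NA fields.
#' @examples
#' normalize_urn("urn:miriam:obo.chebi:CHEBI%3A18021")
#' @export
normalize_urn <- function(uri) {
  m <- regmatches(uri, regexec("^urn:miriam:([^:]+):(.+)$", uri, ignore.case = TRUE))
  out <- data.frame(uri = NA_character_, data_type = NA_character_,
                    identifier = NA_character_, valid = FALSE,
                    stringsAsFactors = FALSE)[rep(1L, length(uri)), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_along(uri)) {
    mi <- m[[i]]
    if (length(mi) != 3L) next
    ns <- tolower(mi[2])
    id <- percent_decode(mi[3])
    out$data_type[i] <- ns
    out$identifier[i] <- id
    out$uri[i] <- paste0("urn:miriam:", ns, ":", percent_encode_id(id))
    out$valid[i] <- TRUE
  }
  out
}

# Parse a date given as ISO-8601 (possibly with time) or dd/MM/yyyy.
# Returns a Date or NA.
parse_flex_date <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(as.Date(NA))
  x <- sub("T.*$", "", trimws(x))
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) return(as.Date(x))
  if (grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)) return(as.Date(x, format = "%d/%m/%Y"))
  as.Date(NA)
}
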