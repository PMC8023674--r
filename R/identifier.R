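#' Compact identifiers (CURIEs)
#'
#' A `mi2cast_identifier` names an entity, ontology term or literature
#' reference as a namespace-prefixed accession, e.g. `uniprotkb:P07948` or
#' `go:0016301`. The prefix is a lower-case registry key; the accession keeps
#' its original case (`CVCL_0030`, `10.1093/x`).
#'
#' @param prefix Namespace token; lower-cased and required to match
#'   `[a-z0-9._-]+`.
#' @param local_id Accession string; non-empty, no whitespace.
#' @return An object of class `mi2cast_identifier`.
#' @examples
#' identifier("go", "0016301")
#' parse_identifier("GO:0016301")
#' curie(parse_identifier("doi:10.1093/x:y"))
#' @export
identifier <- function(prefix, local_id) {
  if (!is.character(prefix) || length(prefix) != 1L || is.na(prefix)) {
    abort_invalid("prefix must be a single string", field = "prefix")
  }
  prefix <- tolower(prefix)
  if (!grepl("^[a-z0-9._-]+$", prefix)) {
    abort_invalid(
      sprintf("prefix '%s' is not a valid namespace token", prefix),
      field = "prefix"
    )
  }
  if (!is.character(local_id) || length(local_id) != 1L || is.na(local_id) ||
      !nzchar(local_id) || grepl("[[:space:]]", local_id)) {
    abort_invalid(
      "local_id must be a non-empty string without whitespace",
      field = "local_id"
    )
  }
  structure(list(prefix = prefix, local_id = local_id),
            class = "mi2cast_identifier")
}

#' @rdname identifier
#' @param curie A string of the form `prefix:accession`; the split is on the
#'   first colon, so DOIs with embedded colons parse correctly.
#' @export
parse_identifier <- function(curie) {
  if (!is.character(curie) || length(curie) != 1L || is.na(curie)) {
    abort_parse("expected a single CURIE string")
  }
  pos <- regexpr(":", curie, fixed = TRUE)
  if (pos < 0L) {
    abort_parse(sprintf("'%s' is not a CURIE (no ':' separator)", curie))
  }
  prefix <- substr(curie, 1L, pos - 1L)
  local <- substr(curie, pos + 1L, nchar(curie))
  if (!nzchar(prefix) || !nzchar(local)) {
    abort_parse(sprintf("'%s' has an empty prefix or accession", curie))
  }
  identifier(prefix, local)
}

#' @rdname identifier
#' @param x An identifier, a CURIE string, or `NULL` (returned as is).
#' @export
as_identifier <- function(x) {
  if (is.null(x)) return(NULL)
  if (is_identifier(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_identifier(x))
  abort_parse("cannot interpret object as an identifier")
}

#' @rdname identifier
#' @export
is_identifier <- function(x) inherits(x, "mi2cast_identifier")

#' @rdname identifier
#' @export
curie <- function(x) {
  if (is.null(x)) return(NA_character_)
  stopifnot(is_identifier(x))
  paste0(x$prefix, ":", x$local_id)
}

#' @export
format.mi2cast_identifier <- function(x, ...) paste0("<", curie(x), ">")

#' @export
print.mi2cast_identifier <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# coerce a list of identifiers/CURIEs; sorted by CURIE for canonical order
as_identifier_list <- function(x, field, distinct = FALSE) {
  if (is.null(x) || length(x) == 0L) return(list())
  if (is_identifier(x)) x <- list(x)
  if (is.character(x)) x <- as.list(x)
  ids <- lapply(x, as_identifier)
  keys <- vapply(ids, curie, character(1))
  if (distinct && anyDuplicated(keys)) {
    abort_invalid(sprintf("%s must be pairwise distinct", field), field = field)
  }
  ids[order(keys, method = "radix")]
}

abort_invalid <- function(message, field) {
  rlang::abort(message, class = "mi2cast_invalid", field = field)
}

abort_parse <- function(message, path = NULL) {
  rlang::abort(message, class = "mi2cast_parse_error", path = path)
}
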