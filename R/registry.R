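#' The identifier-namespace registry
#'
#' The registry mirrors the checklist's entity-type/database table: one row
#' per CURIE namespace with its accession syntax, the interactor type the
#' namespace implies (a UniProtKB accession implies a protein, a ChEBI
#' accession a small molecule), the entity classes it is recommended for,
#' and whether it is the primarily recommended database for those classes or
#' an alternative. It ships as a plain TSV
#' (`system.file("extdata", "registry.tsv", package = "mi2castr")`) so
#' curators can extend it without code changes; accession existence is never
#' checked remotely — syntax only.
#'
#' @param path Optional path to a custom registry TSV with columns
#'   `prefix`, `pattern`, `implied_type`, `entity_types` (pipe-separated),
#'   `rank`, `example`.
#' @return A tibble, one row per namespace.
#' @examples
#' default_registry()
#' @export
default_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.mi2cast_cache$registry)) return(.mi2cast_cache$registry)
    path <- system.file("extdata", "registry.tsv", package = "mi2castr")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL)
  reg <- tibble::as_tibble(raw)
  if (anyDuplicated(reg$prefix)) {
    abort_parse("registry prefixes must be unique")
  }
  for (p in reg$pattern) {
    tryCatch(grepl(p, "x"), error = function(e) {
      abort_parse(sprintf("registry pattern '%s' does not compile", p))
    })
  }
  reg$rank <- factor(reg$rank, levels = c("primary", "alternative"))
  if (cache) .mi2cast_cache$registry <- reg
  reg
}

.mi2cast_cache <- new.env(parent = emptyenv())

#' Check an accession against its namespace syntax
#'
#' Syntax-only quality control for a single identifier: an unknown prefix is
#' reported at INFO level (the checklist does not preclude other databases,
#' provided appropriate ones are used), and an accession that does not match
#' the namespace's published pattern is a WARNING. No findings means the
#' identifier is syntactically clean.
#'
#' @param id An [identifier()] or CURIE string.
#' @param registry A registry tibble, see [default_registry()].
#' @return A findings tibble (possibly empty) with columns `rule_id`,
#'   `severity`, `path`, `message`, `kind`.
#' @examples
#' check_accession_syntax("go:0016301")   # clean
#' check_accession_syntax("go:16301")     # pattern mismatch
#' @export
check_accession_syntax <- function(id, registry = default_registry()) {
  id <- as_identifier(id)
  row <- which(registry$prefix == id$prefix)
  if (length(row) == 0L) {
    return(finding("X.syntax", "INFO", "",
                   sprintf("unknown namespace prefix '%s'", id$prefix),
                   kind = "unknown_prefix"))
  }
  if (!grepl(registry$pattern[row[1]], id$local_id)) {
    return(finding("X.syntax", "WARNING", "",
                   sprintf("accession '%s' does not match the %s pattern",
                           id$local_id, id$prefix),
                   kind = "pattern_mismatch"))
  }
  empty_findings()
}

#' Interactor type implied by a namespace
#'
#' Many databases fix the biological nature of what they identify: a
#' UniProtKB accession names a protein, ChEBI and PubChem name chemicals,
#' the Complex Portal names complexes. Type-ambiguous namespaces (e.g. a
#' gene database used as a protein fallback) imply nothing and return
#' `NULL`; the validator then requires an explicit biological type.
#'
#' @inheritParams check_accession_syntax
#' @return A PSI-MI interactor-type [identifier()], or `NULL`.
#' @examples
#' implied_biological_type("uniprotkb:P07948")  # protein, mi:0326
#' implied_biological_type("ncbigene:4067")     # NULL: gene fallback
#' @export
implied_biological_type <- function(id, registry = default_registry()) {
  id <- as_identifier(id)
  row <- which(registry$prefix == id$prefix)
  if (length(row) == 0L) return(NULL)
  implied <- registry$implied_type[row[1]]
  if (!nzchar(implied)) return(NULL)
  parse_identifier(implied)
}

#' Recommended namespaces for an entity class
#'
#' Returns the registry rows applicable to one entity class, primarily
#' recommended databases first, alternatives after, in stable registry
#' order.
#'
#' @param entity_type One of the registry's entity-class tokens
#'   (case-insensitive), e.g. `"protein"`, `"mRNA"`, `"chemical"`.
#' @inheritParams check_accession_syntax
#' @return A tibble of namespace rows, ordered by rank.
#' @examples
#' allowed_namespaces("chemical")   # chebi before pubchem.compound
#' @export
allowed_namespaces <- function(entity_type, registry = default_registry()) {
  token <- tolower(entity_type)
  types <- strsplit(registry$entity_types, "|", fixed = TRUE)
  known <- sort(unique(unlist(types)))
  known <- known[nzchar(known)]
  if (!token %in% known) {
    rlang::abort(
      sprintf("unknown entity type '%s'; valid types: %s",
              entity_type, paste(known, collapse = ", ")),
      class = "mi2cast_unknown_type"
    )
  }
  keep <- vapply(types, function(t) token %in% t, logical(1))
  out <- registry[keep, , drop = FALSE]
  out[order(out$rank), , drop = FALSE]
}
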