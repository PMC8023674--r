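#' Load an OBO-format term subset
#'
#' Parses the `[Term]` stanzas of an OBO 1.2/1.4 document into an ontology
#' index: a term table plus the `is_a` parent graph and precomputed
#' reflexive-transitive ancestor sets. Only `is_a` edges are read — every
#' branch constraint in the checklist is a subsumption branch — and only the
#' `id`, `name`, `is_a` and `is_obsolete` tags are interpreted. Obsolete
#' terms are retained but flagged. A cycle in the `is_a` graph or an `is_a`
#' target missing from the document is a load error.
#'
#' @param x Path to an OBO file, or the document text (single string or a
#'   character vector of lines).
#' @return An object of class `mi2cast_ontology` with elements `terms`
#'   (tibble: `id`, `name`, `obsolete`), `parents` (named list) and
#'   `ancestors` (named list of reflexive-transitive ancestor CURIEs).
#' @examples
#' idx <- load_obo(c("[Term]", "id: GO:0000001", "name: root"))
#' idx$terms
#' @export
load_obo <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  in_term <- FALSE
  ids <- character()
  names_ <- character()
  obsolete <- logical()
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    key <- norm_term(cur$id)
    ids[[length(ids) + 1L]] <<- key
    names_[[length(names_) + 1L]] <<- cur$name %||% ""
    obsolete[[length(obsolete) + 1L]] <<- isTRUE(cur$obsolete)
    parents[[key]] <<- unique(cur$parents)
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      if (in_term) flush()
      in_term <- identical(ln, "[Term]")
      cur <- list(parents = character())
      next
    }
    if (!in_term || !nzchar(ln) || startsWith(ln, "!")) next
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0L) next
    tag <- substr(ln, 1L, m - 1L)
    val <- trimws(substr(ln, m + 1L, nchar(ln)))
    val <- sub("\\s+!.*$", "", val)  # strip trailing OBO comment
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "is_a") cur$parents <- c(cur$parents, norm_term(val))
    else if (tag == "is_obsolete") cur$obsolete <- identical(val, "true")
  }
  if (in_term) flush()

  if (anyDuplicated(ids)) {
    abort_parse(sprintf("duplicate term id '%s' in OBO document",
                        ids[duplicated(ids)][1]))
  }
  build_ontology_index(ids, names_, obsolete, parents)
}

norm_term <- function(x) curie(parse_identifier(x))

build_ontology_index <- function(ids, names_, obsolete, parents) {
  if (length(ids) == 0L) {
    return(structure(
      list(terms = tibble::tibble(id = character(), name = character(),
                                  obsolete = logical()),
           parents = list(), ancestors = list()),
      class = "mi2cast_ontology"
    ))
  }
  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling) > 0L) {
    abort_parse(sprintf("is_a target '%s' is not defined in the document",
                        dangling[1]))
  }
  # Kahn topological order over is_a (parents first); leftover => cycle
  remaining <- stats::setNames(
    vapply(parents[ids], length, integer(1)), ids)
  children <- split(
    rep(ids, lengths(parents[ids])),
    unlist(parents[ids], use.names = FALSE)
  )
  queue <- ids[remaining == 0L]
  order_ <- character(0)
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    order_ <- c(order_, t)
    for (ch in children[[t]] %||% character()) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_) < length(ids)) {
    member <- setdiff(ids, order_)[1]
    abort_parse(sprintf("is_a cycle detected involving '%s'", member))
  }
  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  for (t in order_) {
    anc <- t
    for (p in parents[[t]]) anc <- c(anc, ancestors[[p]])
    ancestors[[t]] <- unique(anc)
  }
  structure(
    list(
      terms = tibble::tibble(id = ids, name = names_, obsolete = obsolete),
      parents = parents[ids],
      ancestors = ancestors
    ),
    class = "mi2cast_ontology"
  )
}

#' @export
print.mi2cast_ontology <- function(x, ...) {
  roots <- sum(lengths(x$parents) == 0L)
  cat(sprintf("<mi2cast_ontology: %d terms, %d root(s), %d obsolete>\n",
              nrow(x$terms), roots, sum(x$terms$obsolete)))
  invisible(x)
}

#' Merge ontology indexes
#'
#' Combines several loaded subsets (e.g. the bundled mini-ontologies) into
#' one index so branch queries can span vocabularies. Term ids must not
#' collide.
#'
#' @param ... `mi2cast_ontology` objects.
#' @return A merged `mi2cast_ontology`.
#' @export
merge_ontologies <- function(...) {
  idxs <- list(...)
  ids <- unlist(lapply(idxs, function(i) i$terms$id), use.names = FALSE)
  if (anyDuplicated(ids)) {
    abort_parse(sprintf("term '%s' defined in more than one ontology",
                        ids[duplicated(ids)][1]))
  }
  build_ontology_index(
    ids,
    unlist(lapply(idxs, function(i) i$terms$name), use.names = FALSE),
    unlist(lapply(idxs, function(i) i$terms$obsolete), use.names = FALSE),
    do.call(c, lapply(idxs, function(i) i$parents))
  )
}

#' The bundled mini-ontology index
#'
#' Loads and merges the miniature OBO subsets shipped with the package
#' (Relation Ontology causal branch, PSI-MI, ECO, GO, PSI-MOD, SO, ChEBI
#' role branch, BRENDA/Uberon/CL tissue and cell subsets, a synthetic
#' Cellosaurus stand-in, and OBI). These are hand-written test scaffolding
#' covering the term ids the checklist names, not ontology releases.
#'
#' @param dir Optional directory of `.obo` files to load instead of the
#'   bundled ones.
#' @return A merged `mi2cast_ontology`.
#' @export
default_ontology <- function(dir = NULL) {
  if (is.null(dir)) {
    if (!is.null(.mi2cast_cache$ontology)) return(.mi2cast_cache$ontology)
    dir <- system.file("extdata", "obo", package = "mi2castr")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  files <- sort(list.files(dir, pattern = "\\.obo$", full.names = TRUE))
  idx <- do.call(merge_ontologies, lapply(files, load_obo))
  if (cache) .mi2cast_cache$ontology <- idx
  idx
}

#' Branch membership of a term
#'
#' Answers "does this term lie in the branch rooted at any of these terms?"
#' by reflexive-transitive `is_a` traversal: `"yes"` if the term reaches a
#' root, `"no"` if it is indexed but reaches none, and `"unknown"` when the
#' term (or every root) is absent from the index — an unloaded ontology must
#' degrade to "unverifiable", not to an error.
#'
#' @param term Term [identifier()] or CURIE string (or `NULL`).
#' @param roots Character vector of branch-root CURIEs (or identifiers).
#' @param index A `mi2cast_ontology`.
#' @return `"yes"`, `"no"` or `"unknown"`.
#' @examples
#' in_branch("mi:0217", "mi:0407", default_ontology())  # "yes"
#' @export
in_branch <- function(term, roots, index) {
  if (is.null(term)) return("unknown")
  key <- if (is_identifier(term)) curie(term) else
    curie(as_identifier(term))
  roots <- vapply(roots, function(r)
    if (is_identifier(r)) curie(r) else curie(as_identifier(r)),
    character(1), USE.NAMES = FALSE)
  anc <- index$ancestors[[key]]
  known_roots <- roots[roots %in% index$terms$id]
  if (is.null(anc) || length(known_roots) == 0L) return("unknown")
  if (any(known_roots %in% anc)) "yes" else "no"
}

#' Is a branch term used at a non-root level?
#'
#' The checklist asks curators to use the lowest possible (most specific)
#' term. True specificity is context-dependent and not decidable from the
#' graph alone, so this is a deliberately weak proxy: usage is flagged only
#' when the annotated term *is* a branch root, i.e. maximally generic.
#'
#' @inheritParams in_branch
#' @return `TRUE` unless the term equals one of the branch roots.
#' @export
is_most_specific_usage <- function(term, roots, index) {
  key <- curie(as_identifier(term))
  roots <- vapply(roots, function(r) curie(as_identifier(r)), character(1),
                  USE.NAMES = FALSE)
  !key %in% roots
}

is_obsolete_term <- function(term, index) {
  key <- curie(as_identifier(term))
  i <- match(key, index$terms$id)
  !is.na(i) && index$terms$obsolete[i]
}

term_name <- function(term, index) {
  if (is.null(index) || is.null(term)) return(NA_character_)
  key <- curie(as_identifier(term))
  i <- match(key, index$terms$id)
  if (is.na(i)) NA_character_ else index$terms$name[i]
}
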