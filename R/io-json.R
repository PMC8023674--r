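JSON_SCHEMA_VERSION <- "1.0"

#' Canonical JSON serialization
#'
#' The package's lossless interchange dialect: a versioned document
#' (`"mi2cast_schema": "1.0"`) holding an array of statements rendered as
#' nested objects of CURIE strings. Keys appear in a fixed order, empty
#' fields are omitted, and list-valued fields are sorted at construction,
#' so writing is byte-deterministic and `read(write(x))` is the identity on
#' the full model. A machine-readable description of the layout ships at
#' `system.file("extdata", "mi2cast-schema.json", package = "mi2castr")`.
#'
#' @param stmts A list of [causal_statement()] records.
#' @param path Optional file path; when omitted the JSON text is returned.
#' @param pretty Indent the output.
#' @return `write_statements_json()` returns the JSON string (invisibly when
#'   written to a file); `read_statements_json()` returns a list of
#'   statements.
#' @examples
#' txt <- write_statements_json(list(worked_example()))
#' length(read_statements_json(txt))
#' @export
write_statements_json <- function(stmts, path = NULL, pretty = FALSE) {
  doc <- list(
    mi2cast_schema = JSON_SCHEMA_VERSION,
    statements = lapply(stmts, statement_to_list)
  )
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                       pretty = pretty, digits = NA))
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_statements_json
#' @param x A file path or JSON text.
#' @export
read_statements_json <- function(x) {
  if (length(x) == 1L && !grepl("[{\n]", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(x, simplifyVector = FALSE),
    error = function(e) abort_parse(paste("malformed JSON:",
                                          conditionMessage(e)))
  )
  if (!identical(doc$mi2cast_schema, JSON_SCHEMA_VERSION)) {
    abort_parse(sprintf(
      "unsupported schema version '%s' (expected '%s') at path 'mi2cast_schema'",
      doc$mi2cast_schema %||% "<missing>", JSON_SCHEMA_VERSION),
      path = "mi2cast_schema")
  }
  if (is.null(doc$statements)) {
    abort_parse("document has no 'statements' array", path = "statements")
  }
  out <- vector("list", length(doc$statements))
  for (i in seq_along(doc$statements)) {
    out[[i]] <- list_to_statement(doc$statements[[i]],
                                  sprintf("statements[%d]", i))
  }
  out
}

need_field <- function(x, field, path) {
  if (is.null(x[[field]])) {
    abort_parse(sprintf("missing field '%s' at path '%s.%s'",
                        field, path, field),
                path = paste0(path, ".", field))
  }
  x[[field]]
}

list_to_modification <- function(m, path) {
  modification_state(
    modification_type = need_field(m, "modification_type", path),
    residue = m$residue,
    position = m$position
  )
}

list_to_context <- function(ctx, path) {
  if (is.null(ctx)) return(entity_context())
  entity_context(
    biological_activity = ctx$biological_activity,
    modifications = purrr::imap(
      ctx$modifications %||% list(),
      function(m, i) list_to_modification(
        m, sprintf("%s.modifications[%d]", path, i))),
    taxon = ctx$taxon,
    tissue = ctx$tissue,
    cell = ctx$cell,
    compartment = ctx$compartment,
    experimental_setup = unlist(ctx$experimental_setup, use.names = FALSE)
  )
}

list_to_entity <- function(e, path) {
  bio_entity(
    identifier = e$identifier,
    biological_type = e$biological_type,
    components = unlist(e$components, use.names = FALSE),
    context = list_to_context(e$context, paste0(path, ".context"))
  )
}

list_to_statement <- function(s, path) {
  for (field in c("source", "target", "relation", "evidence")) {
    need_field(s, field, path)
  }
  rel <- s$relation
  ev <- s$evidence
  causal_statement(
    source = list_to_entity(s$source, paste0(path, ".source")),
    target = list_to_entity(s$target, paste0(path, ".target")),
    relation = causal_relation(
      relation_term = rel$relation_term,
      mechanism = rel$mechanism,
      target_modification_effect =
        if (!is.null(rel$target_modification_effect))
          list_to_modification(
            rel$target_modification_effect,
            paste0(path, ".relation.target_modification_effect"))
    ),
    evidence = evidence_set(
      references = unlist(ev$references, use.names = FALSE),
      evidence_types = unlist(ev$evidence_types, use.names = FALSE),
      interaction_context = list_to_context(
        ev$interaction_context,
        paste0(path, ".evidence.interaction_context"))
    )
  )
}
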