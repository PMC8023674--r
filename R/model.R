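#' Biological modification state
#'
#' Records one physical modification of an entity (e.g. a phosphorylated
#' residue): a modification type (PSI-MOD for proteins, Sequence Ontology for
#' genes), optionally the modified residue (ChEBI) and its 1-based sequence
#' position. A position without a residue is rejected — a bare number is
#' uninterpretable.
#'
#' @param modification_type Term identifier or CURIE string.
#' @param residue Optional residue term (ChEBI).
#' @param position Optional positive integer, 1-based sequence coordinate.
#' @return An object of class `mi2cast_modification`.
#' @examples
#' modification_state("mod:00048", residue = "chebi:17895", position = 564)
#' @export
modification_state <- function(modification_type, residue = NULL,
                               position = NULL) {
  type <- as_identifier(modification_type)
  if (is.null(type)) {
    abort_invalid("modification_type is required", field = "modification_type")
  }
  residue <- as_identifier(residue)
  if (!is.null(position)) {
    if (!is.numeric(position) || length(position) != 1L || is.na(position) ||
        position != as.integer(position) || position < 1L) {
      abort_invalid("position must be a positive integer (1-based)",
                    field = "position")
    }
    if (is.null(residue)) {
      abort_invalid("position requires a residue to be interpretable",
                    field = "residue")
    }
    position <- as.integer(position)
  }
  structure(
    list(modification_type = type, residue = residue, position = position),
    class = "mi2cast_modification"
  )
}

#' Biological context of an entity or interaction
#'
#' Context fields can be attached at the entity level (on a [bio_entity()])
#' or at the interaction level (on [evidence_set()]); the model stores both
#' and never copies between levels.
#'
#' @param biological_activity Optional activity term (GO molecular function
#'   for proteins/RNA products, ChEBI role for chemicals, SO for genes).
#' @param modifications List of [modification_state()] records describing the
#'   entity's prior state.
#' @param taxon Optional NCBI Taxonomy identifier, e.g. `ncbitaxon:9606`.
#' @param tissue,cell,compartment Optional location terms (BRENDA/Uberon,
#'   CL/Cellosaurus/BRENDA, GO cellular component).
#' @param experimental_setup List of preparation/assay terms (ECO, the PSI-MI
#'   experimental-preparation branch MI:0346, or OBI).
#' @return An object of class `mi2cast_context`.
#' @export
entity_context <- function(biological_activity = NULL, modifications = list(),
                           taxon = NULL, tissue = NULL, cell = NULL,
                           compartment = NULL, experimental_setup = list()) {
  if (inherits(modifications, "mi2cast_modification")) {
    modifications <- list(modifications)
  }
  modifications <- lapply(modifications, function(m) {
    if (!inherits(m, "mi2cast_modification")) {
      abort_invalid("modifications must be modification_state records",
                    field = "modifications")
    }
    m
  })
  mod_key <- vapply(modifications, function(m) {
    paste(curie(m$modification_type), curie(m$residue),
          m$position %||% "", sep = "\r")
  }, character(1))
  structure(
    list(
      biological_activity = as_identifier(biological_activity),
      modifications = modifications[order(mod_key, method = "radix")],
      taxon = as_identifier(taxon),
      tissue = as_identifier(tissue),
      cell = as_identifier(cell),
      compartment = as_identifier(compartment),
      experimental_setup = as_identifier_list(experimental_setup,
                                              "experimental_setup")
    ),
    class = "mi2cast_context"
  )
}

context_is_empty <- function(ctx) {
  is.null(ctx$biological_activity) && length(ctx$modifications) == 0L &&
    is.null(ctx$taxon) && is.null(ctx$tissue) && is.null(ctx$cell) &&
    is.null(ctx$compartment) && length(ctx$experimental_setup) == 0L
}

#' Source or target entity of a causal statement
#'
#' A biomolecule (or phenotype) participating in a causal statement. For
#' families and transient complexes the member identifiers go in
#' `components`, and a biological type (PSI-MI interactor-type branch,
#' MI:0313) is then mandatory to distinguish complex from family.
#'
#' The `identifier` may be `NULL` so that structurally incomplete records can
#' still be parsed and linted; the validator reports the omission
#' (rule R1.entity) rather than the constructor forbidding it.
#'
#' @param identifier Entity identifier (CURIE or [identifier()]), or `NULL`.
#' @param biological_type Optional interactor-type term, e.g. protein
#'   `mi:0326`, complex `mi:0314`.
#' @param components Member identifiers for families/complexes; pairwise
#'   distinct, and require `biological_type` when non-empty.
#' @param context An [entity_context()].
#' @return An object of class `mi2cast_entity`.
#' @export
bio_entity <- function(identifier = NULL, biological_type = NULL,
                       components = list(), context = entity_context()) {
  components <- as_identifier_list(components, "components", distinct = TRUE)
  biological_type <- as_identifier(biological_type)
  if (length(components) > 0L && is.null(biological_type)) {
    abort_invalid(
      "components require a biological_type (complex vs family is ambiguous)",
      field = "biological_type"
    )
  }
  if (!inherits(context, "mi2cast_context")) {
    abort_invalid("context must be an entity_context", field = "context")
  }
  structure(
    list(
      identifier = as_identifier(identifier),
      biological_type = biological_type,
      components = components,
      context = context
    ),
    class = "mi2cast_entity"
  )
}

#' Causal relation of a statement
#'
#' The regulatory effect the source exerts on the target, drawn from the
#' 'causally related to' branch of the Relation Ontology (RO:0002410) or the
#' PSI-MI 'causal statement' branch (MI:2233). A mechanism term (PSI-MI
#' causal regulatory mechanism MI:2245, interaction type MI:0190, or GO
#' biological process) and the modification the mechanism produces on the
#' target can be attached.
#'
#' @param relation_term Relation term, or `NULL` (reported by the validator).
#' @param mechanism Optional interaction-level mechanism term.
#' @param target_modification_effect Optional [modification_state()]: the end
#'   state the mechanism produces on the target.
#' @param allowed_prefixes Namespaces a relation term may come from.
#' @return An object of class `mi2cast_relation`.
#' @export
causal_relation <- function(relation_term = NULL, mechanism = NULL,
                            target_modification_effect = NULL,
                            allowed_prefixes = c("ro", "mi")) {
  relation_term <- as_identifier(relation_term)
  if (!is.null(relation_term) &&
      !relation_term$prefix %in% allowed_prefixes) {
    abort_invalid(
      sprintf("relation_term prefix '%s' is not one of {%s}",
              relation_term$prefix, paste(allowed_prefixes, collapse = ", ")),
      field = "relation_term"
    )
  }
  if (!is.null(target_modification_effect) &&
      !inherits(target_modification_effect, "mi2cast_modification")) {
    abort_invalid("target_modification_effect must be a modification_state",
                  field = "target_modification_effect")
  }
  structure(
    list(
      relation_term = relation_term,
      mechanism = as_identifier(mechanism),
      target_modification_effect = target_modification_effect
    ),
    class = "mi2cast_relation"
  )
}

#' Evidence and provenance of a causal statement
#'
#' One causal statement carries one minimal sufficient evidence set: the
#' references are jointly (conjunctively) interpreted, and independent
#' observations of the same interaction are separate statements sharing a
#' [statement_key()].
#'
#' @param references PubMed/DOI identifiers, pairwise distinct,
#'   order-insignificant.
#' @param evidence_types ECO terms describing how the claim was established.
#' @param interaction_context An [entity_context()] applied at the
#'   interaction level (taxon, tissue, cell, compartment, setup).
#' @return An object of class `mi2cast_evidence`.
#' @export
evidence_set <- function(references = list(), evidence_types = list(),
                         interaction_context = entity_context()) {
  references <- as_identifier_list(references, "references", distinct = TRUE)
  bad <- vapply(references, function(r) !r$prefix %in% c("pubmed", "doi"),
                logical(1))
  if (any(bad)) {
    abort_invalid(
      sprintf("reference prefix must be pubmed or doi (got '%s')",
              references[[which(bad)[1]]]$prefix),
      field = "references"
    )
  }
  if (!inherits(interaction_context, "mi2cast_context")) {
    abort_invalid("interaction_context must be an entity_context",
                  field = "interaction_context")
  }
  structure(
    list(
      references = references,
      evidence_types = as_identifier_list(evidence_types, "evidence_types"),
      interaction_context = interaction_context
    ),
    class = "mi2cast_evidence"
  )
}

#' A causal molecular interaction statement
#'
#' The full record: a source entity whose action influences a target entity,
#' the causal relation between them, and the evidence supporting the claim.
#'
#' @param source,target [bio_entity()] records.
#' @param relation A [causal_relation()].
#' @param evidence An [evidence_set()].
#' @return An object of class `mi2cast_statement`.
#' @seealso [validate()], [worked_example()], [statement_key()]
#' @export
causal_statement <- function(source, target, relation = causal_relation(),
                             evidence = evidence_set()) {
  if (!inherits(source, "mi2cast_entity")) {
    abort_invalid("source must be a bio_entity", field = "source")
  }
  if (!inherits(target, "mi2cast_entity")) {
    abort_invalid("target must be a bio_entity", field = "target")
  }
  if (!inherits(relation, "mi2cast_relation")) {
    abort_invalid("relation must be a causal_relation", field = "relation")
  }
  if (!inherits(evidence, "mi2cast_evidence")) {
    abort_invalid("evidence must be an evidence_set", field = "evidence")
  }
  structure(
    list(source = source, target = target, relation = relation,
         evidence = evidence),
    class = "mi2cast_statement"
  )
}

#' @export
print.mi2cast_statement <- function(x, ...) {
  lbl <- function(id) if (is.null(id)) "?" else curie(id)
  cat("<mi2cast_statement>\n")
  cat("  ", lbl(x$source$identifier), " --[",
      lbl(x$relation$relation_term), "]--> ",
      lbl(x$target$identifier), "\n", sep = "")
  if (!is.null(x$relation$mechanism)) {
    cat("  mechanism:", curie(x$relation$mechanism), "\n")
  }
  if (length(x$evidence$references) > 0L) {
    cat("  references:",
        paste(vapply(x$evidence$references, curie, character(1)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- canonical (serialization-ready) representation --------------------

modification_to_list <- function(m) {
  drop_null(list(
    modification_type = curie(m$modification_type),
    residue = if (!is.null(m$residue)) curie(m$residue),
    position = m$position
  ))
}

context_to_list <- function(ctx) {
  drop_null(list(
    biological_activity = if (!is.null(ctx$biological_activity))
      curie(ctx$biological_activity),
    modifications = if (length(ctx$modifications) > 0L)
      lapply(ctx$modifications, modification_to_list),
    taxon = if (!is.null(ctx$taxon)) curie(ctx$taxon),
    tissue = if (!is.null(ctx$tissue)) curie(ctx$tissue),
    cell = if (!is.null(ctx$cell)) curie(ctx$cell),
    compartment = if (!is.null(ctx$compartment)) curie(ctx$compartment),
    experimental_setup = if (length(ctx$experimental_setup) > 0L)
      vapply(ctx$experimental_setup, curie, character(1))
  ))
}

entity_to_list <- function(e) {
  out <- drop_null(list(
    identifier = if (!is.null(e$identifier)) curie(e$identifier),
    biological_type = if (!is.null(e$biological_type))
      curie(e$biological_type),
    components = if (length(e$components) > 0L)
      vapply(e$components, curie, character(1))
  ))
  ctx <- context_to_list(e$context)
  if (length(ctx) > 0L) out$context <- ctx
  out
}

#' Canonical list form of a statement
#'
#' Deterministic nested-list rendering used by the JSON writer and by
#' [statement_key()]. List-valued fields are already sorted at construction,
#' so identical statements always canonicalize identically.
#'
#' @param stmt A [causal_statement()].
#' @param include_references Drop the reference list when `FALSE` (the key
#'   must not depend on which papers support the claim).
#' @return A nested list of plain strings/integers.
#' @keywords internal
#' @export
statement_to_list <- function(stmt, include_references = TRUE) {
  stopifnot(inherits(stmt, "mi2cast_statement"))
  rel <- drop_null(list(
    relation_term = if (!is.null(stmt$relation$relation_term))
      curie(stmt$relation$relation_term),
    mechanism = if (!is.null(stmt$relation$mechanism))
      curie(stmt$relation$mechanism),
    target_modification_effect =
      if (!is.null(stmt$relation$target_modification_effect))
        modification_to_list(stmt$relation$target_modification_effect)
  ))
  ev <- drop_null(list(
    references = if (include_references && length(stmt$evidence$references))
      vapply(stmt$evidence$references, curie, character(1)),
    evidence_types = if (length(stmt$evidence$evidence_types) > 0L)
      vapply(stmt$evidence$evidence_types, curie, character(1))
  ))
  ictx <- context_to_list(stmt$evidence$interaction_context)
  if (length(ictx) > 0L) ev$interaction_context <- ictx
  list(
    source = entity_to_list(stmt$source),
    target = entity_to_list(stmt$target),
    relation = rel,
    evidence = ev
  )
}

#' Context-sensitive identity key of a statement
#'
#' A deterministic digest over every entity, relation and context field of a
#' statement, excluding the evidence references: the same interaction
#' reported in different papers shares a key, while any difference in
#' entities, relation or context (e.g. a different cell type) yields a
#' distinct key. Distinct contexts are distinct statement instances.
#'
#' @param stmt A [causal_statement()].
#' @return An opaque character scalar.
#' @examples
#' statement_key(worked_example())
#' @export
statement_key <- function(stmt) {
  canon <- statement_to_list(stmt, include_references = FALSE)
  rlang::hash(as.character(jsonlite::toJSON(canon, auto_unbox = TRUE)))
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

`%||%` <- function(a, b) if (is.null(a)) b else a
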