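#' @importFrom rlang %||%
NULL

finding <- function(rule_id, severity, path, message, kind = "other") {
  tibble::tibble(rule_id = rule_id, severity = severity, path = path,
                 message = message, kind = kind)
}

empty_findings <- function() {
  tibble::tibble(rule_id = character(), severity = character(),
                 path = character(), message = character(),
                 kind = character())
}

#' Default branch configuration
#'
#' Names every ontology branch the rule engine consults, as vectors of root
#' CURIEs. Branches whose roots the loaded index does not contain degrade to
#' "unverifiable" INFO findings rather than errors.
#'
#' @return A named list of character vectors of branch-root CURIEs.
#' @export
default_branches <- function() {
  list(
    relation = list(ro = "ro:0002410", psi_mi = "mi:2233"),
    relation_positive = c("ro:0002213", "mi:2234"),
    relation_negative = c("ro:0002212", "mi:2240"),
    evidence = c("eco:0000000"),
    experimental_evidence = c("eco:0000006"),
    setup = c("eco:0000000", "mi:0346", "obi:0000070"),
    activity_protein = c("go:0003674"),
    activity_chemical = c("chebi:50906"),
    activity_gene = c("so:0000110"),
    mechanism = c("mi:2245", "mi:0190", "go:0008150"),
    biotype = c("mi:0313"),
    complex_family = c("mi:0314", "mi:1304"),
    chemical_types = c("mi:0328"),
    gene_types = c("mi:0250"),
    modifying_mechanism = c("mi:0217", "mi:0203", "mi:0220"),
    tissue = c("bto:0000000", "uberon:0000061"),
    cell = c("cl:0000000", "cellosaurus:CVCL_0000", "bto:0000000"),
    compartment = c("go:0005575")
  )
}

#' Configuration of a validation run
#'
#' Bundles everything [validate()] needs: the ontology index, the namespace
#' registry, branch roots, the activity/mechanism equivalence map, and the
#' reporting profile. `profile = "strict"` reports every finding;
#' `"minimum"` keeps only ERRORs, for bulk lint runs.
#'
#' @param profile `"strict"` or `"minimum"`.
#' @param ontology A `mi2cast_ontology`; see [default_ontology()].
#' @param registry Namespace registry tibble; see [default_registry()].
#' @param branches Branch-root configuration; see [default_branches()].
#' @param equivalence Activity/mechanism map; see
#'   [default_equivalence_map()].
#' @return An object of class `mi2cast_config`.
#' @export
rule_config <- function(profile = c("strict", "minimum"),
                        ontology = default_ontology(),
                        registry = default_registry(),
                        branches = default_branches(),
                        equivalence = default_equivalence_map()) {
  profile <- match.arg(profile)
  for (root in unlist(branches, use.names = FALSE)) {
    parse_identifier(root)  # every configured root must be well-formed
  }
  structure(
    list(profile = profile, ontology = ontology, registry = registry,
         branches = branches, equivalence = equivalence),
    class = "mi2cast_config"
  )
}

# membership over several root sets: any yes wins, all no is no, else unknown
membership <- function(term, rootsets, index) {
  if (!is.list(rootsets)) rootsets <- list(rootsets)
  ms <- vapply(rootsets, function(r) in_branch(term, r, index), character(1))
  if (any(ms == "yes")) "yes" else if (all(ms == "no")) "no" else "unknown"
}

unverifiable <- function(path, what) {
  finding("X.unverifiable", "INFO", path,
          sprintf("%s cannot be verified against the loaded ontologies",
                  what),
          kind = "unverifiable")
}

# ---- Rule 1: source and target entities -------------------------------

#' Rule checks
#'
#' The four checklist rules, individually. [validate()] concatenates them
#' (plus the identifier-syntax walk) into a sorted report; the individual
#' checks are exported for targeted use.
#'
#' * **Rule 1** — both entities must carry reference identifiers; an entity
#'   typed as a complex or family must list its components.
#' * **Rule 2** — the causal relation must be present and drawn from the
#'   'causally related to' branch of RO (RO:0002410) or the PSI-MI 'causal
#'   statement' branch (MI:2233); a bare branch root is flagged as
#'   maximally generic.
#' * **Rule 3** — at least one PubMed/DOI reference and at least one ECO
#'   evidence type are mandatory; experimental evidence should come with
#'   experimental-setup terms (ECO, PSI-MI experimental preparation
#'   MI:0346, or OBI).
#' * **Rule 4** — contextual detail: activity or mechanism (4.1), a
#'   biological type whenever the namespace implies none (4.2), the
#'   resulting target modification for modifying mechanisms (4.3), numeric
#'   NCBI Taxonomy ids (4.4), and location terms from their branches (4.5).
#'
#' @param stmt A [causal_statement()].
#' @param cfg A [rule_config()].
#' @return A findings tibble.
#' @name rule-checks
NULL

#' @rdname rule-checks
#' @export
check_rule1 <- function(stmt, cfg = rule_config()) {
  out <- list()
  for (side in c("source", "target")) {
    e <- stmt[[side]]
    if (is.null(e$identifier)) {
      out[[length(out) + 1L]] <- finding(
        "R1.entity", "ERROR", side,
        sprintf("%s entity has no reference identifier", side),
        kind = "absent")
      next
    }
    if (!is.null(e$biological_type) &&
        membership(e$biological_type, cfg$branches$complex_family,
                   cfg$ontology) == "yes" &&
        length(e$components) == 0L) {
      out[[length(out) + 1L]] <- finding(
        "R1.components", "ERROR", paste0(side, ".components"),
        sprintf("%s is typed as a complex/family but lists no components",
                side),
        kind = "absent")
    }
  }
  bind_findings(out)
}

#' @rdname rule-checks
#' @export
check_rule2 <- function(stmt, cfg = rule_config()) {
  term <- stmt$relation$relation_term
  if (is.null(term)) {
    return(finding("R2.relation", "ERROR", "relation.relation_term",
                   "the causal relation of the interaction is not specified",
                   kind = "absent"))
  }
  m <- membership(term, cfg$branches$relation, cfg$ontology)
  if (m == "no") {
    return(finding(
      "R2.relation", "ERROR", "relation.relation_term",
      sprintf("relation term %s is outside the causal-relation branches",
              curie(term)),
      kind = "branch"))
  }
  if (m == "unknown") {
    return(unverifiable("relation.relation_term",
                        sprintf("relation term %s", curie(term))))
  }
  roots <- unlist(cfg$branches$relation, use.names = FALSE)
  if (!is_most_specific_usage(term, roots, cfg$ontology)) {
    return(finding(
      "R2.relation", "WARNING", "relation.relation_term",
      sprintf(
        "relation term %s is a bare branch root (unsigned, undirected); use the most specific term the evidence supports",
        curie(term)),
      kind = "generic"))
  }
  empty_findings()
}

#' @rdname rule-checks
#' @export
check_rule3 <- function(stmt, cfg = rule_config()) {
  out <- list()
  ev <- stmt$evidence
  if (length(ev$references) == 0L) {
    out[[length(out) + 1L]] <- finding(
      "R3.1.reference", "ERROR", "evidence.references",
      "no supporting reference (pubmed/doi) is provided", kind = "absent")
  }
  if (length(ev$evidence_types) == 0L) {
    out[[length(out) + 1L]] <- finding(
      "R3.2.evidence", "ERROR", "evidence.evidence_types",
      "no ECO evidence type is provided", kind = "absent")
  } else {
    for (i in seq_along(ev$evidence_types)) {
      t <- ev$evidence_types[[i]]
      p <- sprintf("evidence.evidence_types[%d]", i)
      m <- membership(t, cfg$branches$evidence, cfg$ontology)
      if (m == "no") {
        out[[length(out) + 1L]] <- finding(
          "R3.2.evidence", "ERROR", p,
          sprintf("evidence type %s is not an ECO term", curie(t)),
          kind = "branch")
      } else if (m == "unknown") {
        out[[length(out) + 1L]] <- unverifiable(
          p, sprintf("evidence type %s", curie(t)))
      }
    }
  }
  experimental <- any(vapply(ev$evidence_types, function(t)
    membership(t, cfg$branches$experimental_evidence,
               cfg$ontology) == "yes", logical(1)))
  setups <- list(
    `source.context.experimental_setup` =
      stmt$source$context$experimental_setup,
    `target.context.experimental_setup` =
      stmt$target$context$experimental_setup,
    `evidence.interaction_context.experimental_setup` =
      ev$interaction_context$experimental_setup
  )
  if (experimental && all(lengths(setups) == 0L)) {
    out[[length(out) + 1L]] <- finding(
      "R3.3.setup", "WARNING",
      "evidence.interaction_context.experimental_setup",
      "experimental evidence is cited but no experimental-setup terms are recorded",
      kind = "absent")
  }
  for (base in names(setups)) {
    terms <- setups[[base]]
    for (i in seq_along(terms)) {
      p <- sprintf("%s[%d]", base, i)
      m <- membership(terms[[i]], cfg$branches$setup, cfg$ontology)
      if (m == "no") {
        out[[length(out) + 1L]] <- finding(
          "R3.3.setup", "WARNING", p,
          sprintf("setup term %s is outside the ECO/MI:0346/OBI branches",
                  curie(terms[[i]])),
          kind = "branch")
      } else if (m == "unknown") {
        out[[length(out) + 1L]] <- unverifiable(
          p, sprintf("setup term %s", curie(terms[[i]])))
      }
    }
  }
  bind_findings(out)
}

# entity class token used to pick the activity branch
entity_type_token <- function(e, cfg) {
  bt <- e$biological_type
  if (is.null(bt) && !is.null(e$identifier)) {
    bt <- implied_biological_type(e$identifier, cfg$registry)
  }
  if (is.null(bt)) return(NA_character_)
  if (membership(bt, cfg$branches$chemical_types, cfg$ontology) == "yes") {
    return("chemical")
  }
  if (membership(bt, cfg$branches$gene_types, cfg$ontology) == "yes") {
    return("gene")
  }
  "protein"
}

activity_rootsets <- function(token, cfg) {
  switch(
    ifelse(is.na(token), "any", token),
    chemical = list(cfg$branches$activity_chemical),
    gene = list(cfg$branches$activity_gene),
    protein = list(cfg$branches$activity_protein),
    any = list(cfg$branches$activity_protein,
               cfg$branches$activity_chemical,
               cfg$branches$activity_gene)
  )
}

#' @rdname rule-checks
#' @export
check_rule4 <- function(stmt, cfg = rule_config()) {
  out <- list()
  b <- cfg$branches
  idx <- cfg$ontology
  rel <- stmt$relation

  # 4.1 activity-or-mechanism
  src_act <- stmt$source$context$biological_activity
  if (is.null(src_act) && is.null(rel$mechanism)) {
    out[[length(out) + 1L]] <- finding(
      "R4.1.mechanism", "WARNING", "relation.mechanism",
      "neither the source activity nor an interaction mechanism is annotated",
      kind = "absent")
  }
  for (side in c("source", "target")) {
    e <- stmt[[side]]
    act <- e$context$biological_activity
    if (is.null(act)) next
    p <- paste0(side, ".context.biological_activity")
    m <- membership(act, activity_rootsets(entity_type_token(e, cfg), cfg),
                    idx)
    if (m == "no") {
      out[[length(out) + 1L]] <- finding(
        "R4.1.activity", "WARNING", p,
        sprintf("activity term %s is outside the branch expected for this entity class",
                curie(act)),
        kind = "branch")
    } else if (m == "unknown") {
      out[[length(out) + 1L]] <- unverifiable(
        p, sprintf("activity term %s", curie(act)))
    }
  }
  if (!is.null(rel$mechanism)) {
    m <- membership(rel$mechanism, b$mechanism, idx)
    if (m == "no") {
      out[[length(out) + 1L]] <- finding(
        "R4.1.mechanism", "WARNING", "relation.mechanism",
        sprintf("mechanism term %s is outside the MI:2245/MI:0190/GO-BP branches",
                curie(rel$mechanism)),
        kind = "branch")
    } else if (m == "unknown") {
      out[[length(out) + 1L]] <- unverifiable(
        "relation.mechanism",
        sprintf("mechanism term %s", curie(rel$mechanism)))
    }
  } else if (!is.null(src_act)) {
    eq <- equivalent_mechanism(src_act, cfg$equivalence)
    if (!is.null(eq)) {
      out[[length(out) + 1L]] <- finding(
        "R4.1.mechanism", "INFO", "relation.mechanism",
        sprintf("source activity %s has the equivalent direct-interaction mechanism %s",
                curie(src_act), curie(eq)),
        kind = "suggestion")
    }
  }

  # 4.2 biological type
  for (side in c("source", "target")) {
    e <- stmt[[side]]
    if (is.null(e$identifier)) next  # reported by R1; nothing to type
    implied <- implied_biological_type(e$identifier, cfg$registry)
    bt <- e$biological_type
    p <- paste0(side, ".biological_type")
    if (is.null(implied) && is.null(bt)) {
      out[[length(out) + 1L]] <- finding(
        "R4.2.biotype", "ERROR", p,
        sprintf("namespace '%s' implies no biological type and none is annotated",
                e$identifier$prefix),
        kind = "absent")
      next
    }
    if (!is.null(bt)) {
      m <- membership(bt, b$biotype, idx)
      if (m == "no") {
        out[[length(out) + 1L]] <- finding(
          "R4.2.biotype", "WARNING", p,
          sprintf("biological type %s is not in the PSI-MI interactor-type branch (MI:0313)",
                  curie(bt)),
          kind = "branch")
      } else if (m == "unknown") {
        out[[length(out) + 1L]] <- unverifiable(
          p, sprintf("biological type %s", curie(bt)))
      }
      if (!is.null(implied) && curie(bt) != curie(implied) &&
          in_branch(bt, curie(implied), idx) != "yes" &&
          in_branch(implied, curie(bt), idx) != "yes") {
        out[[length(out) + 1L]] <- finding(
          "R4.2.biotype", "WARNING", p,
          sprintf("annotated type %s contradicts the type %s implied by namespace '%s'",
                  curie(bt), curie(implied), e$identifier$prefix),
          kind = "contradiction")
      }
    }
  }

  # 4.3 resulting modification for modifying mechanisms
  if (!is.null(rel$mechanism) &&
      membership(rel$mechanism, b$modifying_mechanism, idx) == "yes" &&
      is.null(rel$target_modification_effect) &&
      length(stmt$target$context$modifications) == 0L) {
    out[[length(out) + 1L]] <- finding(
      "R4.3.modification", "WARNING", "relation.target_modification_effect",
      sprintf("mechanism %s modifies the target but no resulting modification state is annotated",
              curie(rel$mechanism)),
      kind = "absent")
  }

  # 4.4 taxa
  taxa <- list(
    `source.context.taxon` = stmt$source$context$taxon,
    `target.context.taxon` = stmt$target$context$taxon,
    `evidence.interaction_context.taxon` =
      stmt$evidence$interaction_context$taxon
  )
  for (p in names(taxa)) {
    t <- taxa[[p]]
    if (is.null(t)) next
    if (t$prefix != "ncbitaxon" || !grepl("^[0-9]+$", t$local_id)) {
      out[[length(out) + 1L]] <- finding(
        "R4.4.taxon", "WARNING", p,
        sprintf("taxon %s is not a numeric NCBI Taxonomy identifier",
                curie(t)),
        kind = "branch")
    }
  }

  # 4.5 locations
  locs <- list(tissue = b$tissue, cell = b$cell, compartment = b$compartment)
  ctxs <- list(source = stmt$source$context, target = stmt$target$context,
               `evidence.interaction_context` =
                 stmt$evidence$interaction_context)
  for (side in names(ctxs)) {
    pref <- if (side == "evidence.interaction_context") side else
      paste0(side, ".context")
    for (fieldname in names(locs)) {
      t <- ctxs[[side]][[fieldname]]
      if (is.null(t)) next
      p <- paste0(pref, ".", fieldname)
      m <- membership(t, locs[[fieldname]], idx)
      if (m == "no") {
        out[[length(out) + 1L]] <- finding(
          "R4.5.location", "WARNING", p,
          sprintf("%s term %s is outside its recommended branch",
                  fieldname, curie(t)),
          kind = "branch")
      } else if (m == "unknown") {
        out[[length(out) + 1L]] <- unverifiable(
          p, sprintf("%s term %s", fieldname, curie(t)))
      }
    }
  }
  bind_findings(out)
}

# ---- identifier syntax walk -------------------------------------------

collect_identifiers <- function(stmt) {
  acc <- list()
  push <- function(path, id, role) {
    if (!is.null(id)) acc[[length(acc) + 1L]] <<- list(path = path, id = id,
                                                       role = role)
  }
  ctx_walk <- function(ctx, pref) {
    push(paste0(pref, ".biological_activity"), ctx$biological_activity,
         "term")
    for (i in seq_along(ctx$modifications)) {
      m <- ctx$modifications[[i]]
      push(sprintf("%s.modifications[%d].modification_type", pref, i),
           m$modification_type, "term")
      push(sprintf("%s.modifications[%d].residue", pref, i), m$residue,
           "term")
    }
    push(paste0(pref, ".taxon"), ctx$taxon, "term")
    push(paste0(pref, ".tissue"), ctx$tissue, "term")
    push(paste0(pref, ".cell"), ctx$cell, "term")
    push(paste0(pref, ".compartment"), ctx$compartment, "term")
    for (i in seq_along(ctx$experimental_setup)) {
      push(sprintf("%s.experimental_setup[%d]", pref, i),
           ctx$experimental_setup[[i]], "term")
    }
  }
  for (side in c("source", "target")) {
    e <- stmt[[side]]
    push(paste0(side, ".identifier"), e$identifier, "entity")
    push(paste0(side, ".biological_type"), e$biological_type, "term")
    for (i in seq_along(e$components)) {
      push(sprintf("%s.components[%d]", side, i), e$components[[i]],
           "entity")
    }
    ctx_walk(e$context, paste0(side, ".context"))
  }
  push("relation.relation_term", stmt$relation$relation_term, "term")
  push("relation.mechanism", stmt$relation$mechanism, "term")
  tme <- stmt$relation$target_modification_effect
  if (!is.null(tme)) {
    push("relation.target_modification_effect.modification_type",
         tme$modification_type, "term")
    push("relation.target_modification_effect.residue", tme$residue, "term")
  }
  for (i in seq_along(stmt$evidence$references)) {
    push(sprintf("evidence.references[%d]", i),
         stmt$evidence$references[[i]], "reference")
  }
  for (i in seq_along(stmt$evidence$evidence_types)) {
    push(sprintf("evidence.evidence_types[%d]", i),
         stmt$evidence$evidence_types[[i]], "term")
  }
  ctx_walk(stmt$evidence$interaction_context,
           "evidence.interaction_context")
  acc
}

check_syntax <- function(stmt, cfg) {
  out <- list()
  for (item in collect_identifiers(stmt)) {
    f <- check_accession_syntax(item$id, cfg$registry)
    if (nrow(f) > 0L) {
      f$path <- item$path
      out[[length(out) + 1L]] <- f
    }
    if (item$role == "entity" && item$id$prefix == "uniprotkb") {
      out[[length(out) + 1L]] <- finding(
        "X.syntax", "INFO", item$path,
        "prefer a reviewed (Swiss-Prot) accession over TrEMBL when one exists; not decidable from syntax",
        kind = "review_status")
    }
    if (item$role == "term" && is_obsolete_term(item$id, cfg$ontology)) {
      out[[length(out) + 1L]] <- finding(
        "X.obsolete", "WARNING", item$path,
        sprintf("term %s is obsolete in the loaded ontology",
                curie(item$id)),
        kind = "obsolete")
    }
  }
  bind_findings(out)
}

bind_findings <- function(lst) {
  if (length(lst) == 0L) return(empty_findings())
  dplyr::bind_rows(lst)
}

# ---- the validator -----------------------------------------------------

#' Validate a causal statement against the checklist
#'
#' Runs Rules 1-4 plus the identifier-syntax walk and returns an ordered
#' validation report: a tibble of findings (`rule_id`, `severity`, `path`,
#' `message`, `kind`) sorted by `(path, rule_id)`, carrying the statement's
#' [statement_key()] as an attribute. Validation is a pure function of the
#' statement and configuration: identical inputs give identical reports.
#' ERROR findings correspond exactly to violated "must" clauses; WARNINGs to
#' "should/recommended"; INFO findings are advisory (unverifiable terms,
#' style reminders, equivalence suggestions).
#'
#' @param stmt A [causal_statement()].
#' @param cfg A [rule_config()].
#' @return A `mi2cast_report` tibble.
#' @examples
#' validate(worked_example())
#' @export
validate <- function(stmt, cfg = rule_config()) {
  stopifnot(inherits(stmt, "mi2cast_statement"))
  f <- dplyr::bind_rows(
    check_rule1(stmt, cfg),
    check_rule2(stmt, cfg),
    check_rule3(stmt, cfg),
    check_rule4(stmt, cfg),
    check_syntax(stmt, cfg)
  )
  f <- dplyr::arrange(f, path, rule_id)
  if (cfg$profile == "minimum") {
    f <- dplyr::filter(f, .data$severity == "ERROR")
  }
  structure(f, class = c("mi2cast_report", class(f)),
            statement_ref = statement_key(stmt))
}

#' Validate a batch of statements
#'
#' @param stmts A list of [causal_statement()] records.
#' @param cfg A [rule_config()].
#' @return A tibble of findings with leading `statement` (index) and
#'   `statement_key` columns.
#' @export
validate_corpus <- function(stmts, cfg = rule_config()) {
  rows <- purrr::imap(stmts, function(s, i) {
    r <- validate(s, cfg)
    if (nrow(r) == 0L) return(NULL)
    tibble::tibble(statement = i,
                   statement_key = attr(r, "statement_ref"),
                   tibble::as_tibble(r))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(statement = integer(), statement_key = character(),
                          empty_findings())
  }
  out
}

#' @export
print.mi2cast_report <- function(x, ...) {
  cat(sprintf("<mi2cast_report: %d finding(s), compliance: %s>\n",
              nrow(x), compliance_level(x)))
  if (nrow(x) > 0L) print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Compliance level of a validation report
#'
#' Summarizes a report into one of three grades: `non_compliant` (any ERROR
#' — an essential Rule 1-3 item or conditional must is missing), `minimum`
#' (no ERROR, but at least one Rule 4 context item is absent), or
#' `context_enriched` (neither).
#'
#' @param report A `mi2cast_report` or findings tibble.
#' @return A character scalar.
#' @export
compliance_level <- function(report) {
  if (nrow(report) == 0L) return("context_enriched")
  if (any(report$severity == "ERROR")) return("non_compliant")
  absent_r4 <- report$severity == "WARNING" & report$kind == "absent" &
    startsWith(report$rule_id, "R4.")
  if (any(absent_r4)) "minimum" else "context_enriched"
}

#' Activity/mechanism equivalence mapping
#'
#' For direct interactions the source's molecular activity and the PSI-MI
#' direct-interaction mechanism are interchangeable views of the same event
#' (kinase activity, GO:0016301, corresponds to a phosphorylation reaction,
#' MI:0217). The mapping ships as an extensible TSV and is enforced
#' bijective at load, so the inverse lookup is always well-defined.
#'
#' @param path Optional custom two-column TSV (`activity`, `mechanism`).
#' @return A tibble with columns `activity` and `mechanism` (CURIEs).
#' @export
default_equivalence_map <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.mi2cast_cache$eqmap)) return(.mi2cast_cache$eqmap)
    path <- system.file("extdata", "activity_mechanism.tsv",
                        package = "mi2castr")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  map <- tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
  if (anyDuplicated(map$activity) || anyDuplicated(map$mechanism)) {
    abort_parse("activity/mechanism map must be bijective")
  }
  if (cache) .mi2cast_cache$eqmap <- map
  map
}

#' @rdname default_equivalence_map
#' @param activity_term,mechanism_term Term [identifier()] or CURIE string.
#' @param map An equivalence map tibble.
#' @return `equivalent_mechanism()`/`equivalent_activity()` return the
#'   mapped term identifier, or `NULL` when unmapped.
#' @examples
#' equivalent_mechanism("go:0016301")  # mi:0217
#' @export
equivalent_mechanism <- function(activity_term,
                                 map = default_equivalence_map()) {
  key <- curie(as_identifier(activity_term))
  i <- match(key, map$activity)
  if (is.na(i)) NULL else parse_identifier(map$mechanism[i])
}

#' @rdname default_equivalence_map
#' @export
equivalent_activity <- function(mechanism_term,
                                map = default_equivalence_map()) {
  key <- curie(as_identifier(mechanism_term))
  i <- match(key, map$mechanism)
  if (is.na(i)) NULL else parse_identifier(map$activity[i])
}

#' The rule catalogue
#'
#' One row per finding id the engine can emit: its maximum severity and the
#' checklist clause it enforces. "must" clauses (including the conditional
#' musts inside recommended rules) map to ERROR, "should/recommended" to
#' WARNING, advisory and unverifiable checks to INFO.
#'
#' @return A tibble with columns `rule_id`, `severity`, `clause`.
#' @export
rule_catalogue <- function() {
  tibble::tribble(
    ~rule_id, ~severity, ~clause,
    "R1.entity", "ERROR",
    "source and target entities must carry reference identifiers",
    "R1.components", "ERROR",
    "complex/family entities must list their component identifiers",
    "R2.relation", "ERROR",
    "the causal relation must come from RO:0002410 or MI:2233; roots are flagged as generic",
    "R3.1.reference", "ERROR",
    "the full minimal set of supporting publications (pubmed/doi) must be given",
    "R3.2.evidence", "ERROR",
    "the evidence type must be given as ECO terms",
    "R3.3.setup", "WARNING",
    "experimental evidence should record setup terms (ECO, MI:0346, OBI)",
    "R4.1.activity", "WARNING",
    "entity activities should come from GO-MF / ChEBI role / SO by entity class",
    "R4.1.mechanism", "WARNING",
    "an activity or a mechanism (MI:2245, MI:0190, GO-BP) should be annotated",
    "R4.2.biotype", "ERROR",
    "entities on type-ambiguous namespaces must state their biological type (MI:0313 branch)",
    "R4.3.modification", "WARNING",
    "modifying mechanisms should state the resulting target modification",
    "R4.4.taxon", "WARNING",
    "taxa should be numeric NCBI Taxonomy identifiers",
    "R4.5.location", "WARNING",
    "tissue/cell/compartment terms should come from their recommended branches",
    "X.syntax", "WARNING",
    "accessions should match their namespace syntax; unknown prefixes and review-status reminders are INFO",
    "X.unverifiable", "INFO",
    "terms that no loaded ontology can confirm are reported, not rejected",
    "X.obsolete", "WARNING",
    "obsolete ontology terms are flagged"
  )
}
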