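VIOLATION_RULES <- c("R1.entity", "R1.components", "R2.relation",
                     "R3.1.reference", "R3.2.evidence", "R4.2.biotype",
                     "R4.3.modification", "X.syntax")

normalize_rates <- function(rates) {
  full <- stats::setNames(rep(0, length(VIOLATION_RULES)), VIOLATION_RULES)
  if (is.null(rates) || length(rates) == 0L) return(full)
  for (nm in names(rates)) {
    hit <- VIOLATION_RULES[VIOLATION_RULES == nm |
                             startsWith(VIOLATION_RULES, paste0(nm, "."))]
    if (length(hit) != 1L) {
      rlang::abort(sprintf("unknown or ambiguous violation rule '%s'", nm))
    }
    r <- rates[[nm]]
    if (!is.numeric(r) || r < 0 || r > 1) {
      rlang::abort(sprintf("rate for %s must be in [0, 1]", nm))
    }
    full[[hit]] <- r
  }
  full
}

rand_uniprot <- function() {
  paste0(sample(c("O", "P", "Q"), 1L),
         sample(0:9, 1L),
         paste(sample(c(LETTERS, 0:9), 3L, replace = TRUE), collapse = ""),
         sample(0:9, 1L))
}

rand_pubmed <- function() {
  paste0("pubmed:", sample.int(29999999L, 1L) + 1000000L)
}

#' Generate synthetic causal statements with seeded rule violations
#'
#' Produces `n` statements drawn from the bundled fixture vocabularies
#' (UniProtKB/NCBI-gene/ChEBI/Complex Portal entities, relation terms under
#' RO:0002410 and MI:2233, ECO evidence with MI:0346 setup terms, GO/ChEBI
#' activities and modifications) together with an exact ground truth of the
#' violations injected. Each violation is a minimal single-field corruption:
#' a dropped target identifier (R1.entity), a complex with no components
#' (R1.components), a relation term swapped into a wrong branch
#' (R2.relation), a dropped reference list (R3.1) or evidence-type list
#' (R3.2), a dropped biological type on a fallback-namespace entity (R4.2),
#' a modifying mechanism without its resulting modification (R4.3), and a
#' malformed accession (X.syntax). Statements generated with all rates zero
#' validate with no ERROR or WARNING findings, so on any generated corpus
#' the validator's (statement, rule_id, path) findings at those severities
#' should reproduce the ground truth exactly.
#'
#' When both R1.entity and R4.2.biotype are drawn for one statement, only
#' R1.entity is injected: the validator deliberately skips per-entity checks
#' on an identifier-less entity, so the type violation would be
#' unobservable.
#'
#' @param n Number of statements (>= 0).
#' @param rates Named numeric vector of per-rule violation probabilities in
#'   `[0, 1]`; names may be abbreviated to the rule prefix (`"R3.1"`).
#'   Unnamed rules default to 0.
#' @param seed Integer seed; the generator uses one private RNG stream and
#'   is byte-reproducible for a fixed seed.
#' @return A list with `statements` (list of [causal_statement()]) and
#'   `ground_truth` (tibble: `statement`, `rule_id`, `path`).
#' @examples
#' g <- generate_statements(5, rates = c(R3.1 = 0.5), seed = 1)
#' g$ground_truth
#' @export
generate_statements <- function(n, rates = NULL, seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == as.integer(n))
  rates <- normalize_rates(rates)
  withr::with_seed(as.integer(seed), {
    stmts <- vector("list", n)
    gt <- vector("list", n)
    for (i in seq_len(n)) {
      g <- generate_one(rates)
      stmts[[i]] <- g$stmt
      if (length(g$violations) > 0L) {
        gt[[i]] <- tibble::tibble(
          statement = i,
          rule_id = vapply(g$violations, `[[`, "", 1L),
          path = vapply(g$violations, `[[`, "", 2L)
        )
      }
    }
    truth <- dplyr::bind_rows(gt)
    if (nrow(truth) == 0L) {
      truth <- tibble::tibble(statement = integer(), rule_id = character(),
                              path = character())
    }
    list(statements = stmts, ground_truth = truth)
  })
}

generate_one <- function(rates) {
  flags <- stats::runif(length(VIOLATION_RULES)) < rates
  names(flags) <- VIOLATION_RULES
  viol <- list()
  note <- function(rule, path) {
    viol[[length(viol) + 1L]] <<- list(rule, path)
  }

  taxon <- sample(c("ncbitaxon:9606", "ncbitaxon:10090"), 1L)
  activities <- c("go:0016301", "go:0003700", "go:0004725")

  # --- source entity ---------------------------------------------------
  if (flags[["R1.components"]]) {
    src_prefix <- "complexportal"
    src_local <- sprintf("CPX-%d", sample.int(9999L, 1L))
    src_type <- "mi:0314"
    src_components <- list()
    note("R1.components", "source.components")
  } else {
    flavor <- sample(c("uniprot", "gene_fallback", "complex", "chemical"),
                     1L, prob = c(0.5, 0.2, 0.15, 0.15))
    if (flavor == "uniprot") {
      src_prefix <- "uniprotkb"; src_local <- rand_uniprot()
      src_type <- NULL
    } else if (flavor == "gene_fallback") {
      src_prefix <- "ncbigene"
      src_local <- as.character(sample.int(99999L, 1L))
      src_type <- "mi:0326"
    } else if (flavor == "complex") {
      src_prefix <- "complexportal"
      src_local <- sprintf("CPX-%d", sample.int(9999L, 1L))
      src_type <- "mi:0314"
    } else {
      src_prefix <- "chebi"
      src_local <- as.character(sample.int(999999L, 1L))
      src_type <- NULL
    }
    src_components <- if (src_prefix == "complexportal") {
      lapply(seq_len(sample(2:3, 1L)),
             function(.) identifier("uniprotkb", rand_uniprot()))
    } else {
      list()
    }
  }
  if (flags[["X.syntax"]]) {
    src_local <- "XXINVALIDXX"
    note("X.syntax", "source.identifier")
  }
  src_activity <- if (src_prefix == "chebi") "chebi:35223" else
    sample(activities, 1L)
  src_ctx <- entity_context(
    biological_activity = src_activity,
    modifications = if (src_prefix == "uniprotkb" &&
                        stats::runif(1) < 0.3) {
      list(modification_state("mod:00046", residue = "chebi:17115",
                              position = sample.int(500L, 1L)))
    } else {
      list()
    },
    taxon = taxon,
    compartment = if (stats::runif(1) < 0.4)
      sample(c("go:0005634", "go:0005737"), 1L),
    experimental_setup = "mi:0506"
  )
  source <- bio_entity(identifier(src_prefix, src_local),
                       biological_type = src_type,
                       components = src_components, context = src_ctx)

  # --- target entity ---------------------------------------------------
  drop_target <- flags[["R1.entity"]]
  tgt_fallback <- flags[["R4.2.biotype"]] || stats::runif(1) < 0.25
  if (tgt_fallback) {
    tgt_id <- identifier("ncbigene", as.character(sample.int(99999L, 1L)))
    tgt_type <- "mi:0326"
  } else {
    tgt_id <- identifier("uniprotkb", rand_uniprot())
    tgt_type <- NULL
  }
  if (drop_target) {
    tgt_id <- NULL
    note("R1.entity", "target")
  } else if (flags[["R4.2.biotype"]]) {
    tgt_type <- NULL
    note("R4.2.biotype", "target.biological_type")
  }
  tgt_ctx <- entity_context(
    biological_activity = sample(activities, 1L),
    taxon = taxon,
    tissue = if (stats::runif(1) < 0.3)
      sample(c("bto:0000089", "uberon:0002107"), 1L),
    cell = if (stats::runif(1) < 0.3)
      sample(c("cl:0000236", "cellosaurus:CVCL_0030"), 1L)
  )
  target <- bio_entity(tgt_id, biological_type = tgt_type,
                       context = tgt_ctx)

  # --- relation --------------------------------------------------------
  modifying <- flags[["R4.3.modification"]] || stats::runif(1) < 0.5
  if (modifying) {
    mech <- sample(c("mi:0217", "mi:0203", "mi:0220"), 1L)
    resmod <- modification_state(
      sample(c("mod:00046", "mod:00047", "mod:00048"), 1L),
      residue = sample(c("chebi:17115", "chebi:16857", "chebi:17895"), 1L),
      position = sample.int(1000L, 1L)
    )
  } else {
    mech <- sample(c("mi:2247", "mi:2249", "go:0051170"), 1L)
    resmod <- NULL
  }
  if (flags[["R4.3.modification"]]) {
    resmod <- NULL
    note("R4.3.modification", "relation.target_modification_effect")
  }
  rel_term <- sample(c("ro:0002629", "ro:0002630", "ro:0002213",
                       "ro:0002212", "mi:2236", "mi:2241"), 1L)
  if (flags[["R2.relation"]]) {
    rel_term <- "mi:0326"  # interactor-type branch: wrong vocabulary
    note("R2.relation", "relation.relation_term")
  }
  relation <- causal_relation(rel_term, mechanism = mech,
                              target_modification_effect = resmod)

  # --- evidence --------------------------------------------------------
  refs <- unique(replicate(sample(1:2, 1L), rand_pubmed()))
  if (flags[["R3.1.reference"]]) {
    refs <- list()
    note("R3.1.reference", "evidence.references")
  }
  ev_types <- sample(c("eco:0000006", "eco:0005805"), 1L)
  if (flags[["R3.2.evidence"]]) {
    ev_types <- list()
    note("R3.2.evidence", "evidence.evidence_types")
  }
  evidence <- evidence_set(
    references = refs,
    evidence_types = ev_types,
    interaction_context = entity_context(
      taxon = if (stats::runif(1) < 0.5) taxon
    )
  )

  list(stmt = causal_statement(source, target, relation, evidence),
       violations = viol)
}

#' The kinase/phosphatase worked example
#'
#' The classic fully annotated causal statement: the kinase activity of the
#' protein LYN (UniProtKB P07948) directly and positively regulates the
#' protein tyrosine phosphatase PTPN6 (UniProtKB P29350) through a
#' phosphorylation reaction (MI:0217) that leaves an
#' O4'-phospho-L-tyrosine (MOD:00048) at sequence position 564, stimulating
#' PTPN6's phosphatase activity; supported by one PubMed reference
#' (placeholder accession, illustrative) and experimental evidence
#' (ECO:0000006). It validates with zero ERROR findings under the bundled
#' fixtures.
#'
#' @return A [causal_statement()].
#' @examples
#' validate(worked_example())
#' @export
worked_example <- function() {
  causal_statement(
    source = bio_entity(
      "uniprotkb:P07948",
      context = entity_context(
        biological_activity = "go:0016301",
        taxon = "ncbitaxon:9606",
        experimental_setup = "mi:0506"
      )
    ),
    target = bio_entity(
      "uniprotkb:P29350",
      context = entity_context(
        biological_activity = "go:0004725",
        taxon = "ncbitaxon:9606",
        cell = "cl:0000236"
      )
    ),
    relation = causal_relation(
      "ro:0002629",
      mechanism = "mi:0217",
      target_modification_effect = modification_state(
        "mod:00048", residue = "chebi:17895", position = 564L)
    ),
    evidence = evidence_set(
      references = "pubmed:10068674",
      evidence_types = "eco:0000006"
    )
  )
}
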