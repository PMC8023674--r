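test_that("a fully annotated statement has no ERROR findings", {
  r <- validate(minimal_valid_statement(), CFG)
  expect_equal(nrow(error_findings(r)), 0L)
})

test_that("rule 1 requires identifiers and complex components", {
  s <- minimal_valid_statement()
  s$target <- bio_entity(NULL)
  f <- check_rule1(s, CFG)
  expect_equal(f$rule_id, "R1.entity")
  expect_equal(f$path, "target")
  expect_equal(f$severity, "ERROR")

  cx <- bio_entity("complexportal:CPX-1861", biological_type = "mi:0314",
                   components = c("uniprotkb:P07948", "uniprotkb:P29350"))
  s <- minimal_valid_statement(); s$source <- cx
  expect_equal(nrow(check_rule1(s, CFG)), 0L)

  cx_empty <- bio_entity("complexportal:CPX-1861",
                         biological_type = "mi:0314")
  s$source <- cx_empty
  f <- check_rule1(s, CFG)
  expect_equal(f$rule_id, "R1.components")
  expect_equal(f$path, "source.components")
})

test_that("rule 2 enforces the causal-relation branches", {
  s <- minimal_valid_statement()
  expect_equal(nrow(check_rule2(s, CFG)), 0L)

  s$relation <- causal_relation("mi:0326", mechanism = "mi:2247")
  f <- check_rule2(s, CFG)
  expect_equal(f$severity, "ERROR")
  expect_equal(f$rule_id, "R2.relation")

  s$relation <- causal_relation(NULL, mechanism = "mi:2247")
  expect_equal(check_rule2(s, CFG)$severity, "ERROR")

  # a bare branch root is unsigned/undirected: generic-usage warning
  s$relation <- causal_relation("ro:0002410", mechanism = "mi:2247")
  f <- check_rule2(s, CFG)
  expect_equal(f$severity, "WARNING")
  expect_equal(f$kind, "generic")

  # unknown vocabulary degrades to unverifiable, not to an error
  s$relation <- causal_relation("ro:9999999", mechanism = "mi:2247")
  expect_equal(check_rule2(s, CFG)$rule_id, "X.unverifiable")
})

test_that("rule 3 requires provenance and ECO evidence", {
  s <- minimal_valid_statement()
  expect_equal(nrow(check_rule3(s, CFG)), 0L)

  s$evidence <- evidence_set(evidence_types = "eco:0000204")
  f <- check_rule3(s, CFG)
  expect_equal(f$rule_id, "R3.1.reference")
  expect_equal(f$severity, "ERROR")

  s$evidence <- evidence_set(references = "pubmed:1")
  f <- check_rule3(s, CFG)
  expect_equal(f$rule_id, "R3.2.evidence")

  # a non-ECO evidence term is an error at its own position
  s$evidence <- evidence_set(references = "pubmed:1",
                             evidence_types = "go:0008150")
  f <- check_rule3(s, CFG)
  expect_equal(f$rule_id, "R3.2.evidence")
  expect_equal(f$path, "evidence.evidence_types[1]")

  # experimental evidence without setup terms is a warning ...
  s$evidence <- evidence_set(references = "pubmed:1",
                             evidence_types = "eco:0005805")
  f <- check_rule3(s, CFG)
  expect_equal(f$rule_id, "R3.3.setup")
  expect_equal(f$severity, "WARNING")

  # ... cleared by setup terms on any participant (e.g. overexpressed source)
  s$source$context <- entity_context(biological_activity = "go:0016301",
                                     experimental_setup = "mi:0506")
  expect_equal(nrow(check_rule3(s, CFG)), 0L)

  # author statements need no experimental setup
  s2 <- minimal_valid_statement()
  expect_equal(nrow(check_rule3(s2, CFG)), 0L)
})

test_that("rule 4.1 asks for an activity or a mechanism", {
  s <- minimal_valid_statement()
  s$source$context <- entity_context()
  s$relation <- causal_relation("ro:0002629")
  f <- check_rule4(s, CFG)
  expect_true(any(f$rule_id == "R4.1.mechanism" & f$kind == "absent"))

  # activity alone suffices, and a known equivalence is suggested as INFO
  s$source$context <- entity_context(biological_activity = "go:0016301")
  f <- check_rule4(s, CFG)
  expect_false(any(f$kind == "absent"))
  info <- f[f$kind == "suggestion", ]
  expect_equal(info$severity, "INFO")
  expect_match(info$message, "mi:0217")

  # activities are checked against the branch for the entity class
  s <- minimal_valid_statement()
  s$source$context <- entity_context(biological_activity = "go:0008150")
  f <- check_rule4(s, CFG)
  expect_true(any(f$rule_id == "R4.1.activity" & f$severity == "WARNING"))

  # chemicals use the ChEBI role branch
  chem <- bio_entity("chebi:29101",
                     context = entity_context(
                       biological_activity = "chebi:35223"))
  s$source <- chem
  f <- check_rule4(s, CFG)
  expect_false(any(f$rule_id == "R4.1.activity"))
})

test_that("rule 4.2 requires a type exactly when the namespace implies none", {
  s <- minimal_valid_statement()
  s$source <- bio_entity("ncbigene:4067")
  f <- check_rule4(s, CFG)
  err <- f[f$severity == "ERROR", ]
  expect_equal(err$rule_id, "R4.2.biotype")
  expect_equal(err$path, "source.biological_type")

  # annotating 'protein' clears it
  s$source <- bio_entity("ncbigene:4067", biological_type = "mi:0326")
  f <- check_rule4(s, CFG)
  expect_equal(nrow(f[f$severity == "ERROR", ]), 0L)

  # a type contradicting the namespace-implied type is a warning
  s$source <- bio_entity("uniprotkb:P07948", biological_type = "mi:0328")
  f <- check_rule4(s, CFG)
  expect_true(any(f$kind == "contradiction"))

  # a type outside the interactor-type branch is flagged
  s$source <- bio_entity("ncbigene:4067", biological_type = "mi:2247")
  f <- check_rule4(s, CFG)
  expect_true(any(f$rule_id == "R4.2.biotype" & f$kind == "branch"))
})

test_that("rule 4.3 wants the resulting modification of modifying mechanisms", {
  s <- minimal_valid_statement()
  s$relation <- causal_relation("ro:0002629", mechanism = "mi:0217")
  f <- check_rule4(s, CFG)
  expect_true(any(f$rule_id == "R4.3.modification"))

  s$relation <- causal_relation(
    "ro:0002629", mechanism = "mi:0217",
    target_modification_effect = modification_state(
      "mod:00048", residue = "chebi:17895", position = 564))
  f <- check_rule4(s, CFG)
  expect_false(any(f$rule_id == "R4.3.modification"))

  # non-modifying mechanisms are exempt
  s$relation <- causal_relation("ro:0002629", mechanism = "mi:2247")
  f <- check_rule4(s, CFG)
  expect_false(any(f$rule_id == "R4.3.modification"))
})

test_that("rules 4.4 and 4.5 check taxa and locations", {
  s <- minimal_valid_statement()
  s$source$context <- entity_context(biological_activity = "go:0016301",
                                     taxon = "ncbitaxon:9606")
  expect_false(any(check_rule4(s, CFG)$rule_id == "R4.4.taxon"))

  s$source$context <- entity_context(biological_activity = "go:0016301",
                                     taxon = "taxonomy:9606")
  expect_true(any(check_rule4(s, CFG)$rule_id == "R4.4.taxon"))

  s$source$context <- entity_context(biological_activity = "go:0016301",
                                     compartment = "go:0008150")
  f <- check_rule4(s, CFG)
  expect_true(any(f$rule_id == "R4.5.location" & f$severity == "WARNING"))

  # translocation: origin compartment on the entity, destination as mechanism
  s <- minimal_valid_statement()
  s$relation <- causal_relation("ro:0002629", mechanism = "go:0051170")
  s$target$context <- entity_context(compartment = "go:0005737")
  f <- check_rule4(s, CFG)
  expect_false(any(f$severity %in% c("ERROR", "WARNING")))
})

test_that("the syntax walk covers nested identifiers and obsolete terms", {
  s <- minimal_valid_statement()
  s$source <- bio_entity("uniprotkb:BADACC",
                         context = entity_context(
                           biological_activity = "go:0016301"))
  r <- validate(s, CFG)
  expect_true(any(r$rule_id == "X.syntax" & r$path == "source.identifier" &
                    r$kind == "pattern_mismatch"))

  s <- minimal_valid_statement()
  s$relation <- causal_relation("ro:0002629", mechanism = "mi:0999")
  r <- validate(s, CFG)
  expect_true(any(r$rule_id == "X.obsolete" & r$path == "relation.mechanism"))
})

test_that("validation is deterministic and sorted by (path, rule_id)", {
  g <- generate_statements(20, rates = c(R2.relation = 0.4, R3.1 = 0.4),
                           seed = 5)
  for (s in g$statements) {
    r1 <- validate(s, CFG)
    r2 <- validate(s, CFG)
    expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
    ord <- order(r1$path, r1$rule_id, method = "radix")
    expect_identical(ord, seq_len(nrow(r1)))
  }
})

test_that("adding a valid optional field never introduces an ERROR", {
  base <- minimal_valid_statement()
  n0 <- nrow(error_findings(validate(base, CFG)))
  enrich <- list(
    function(s) { s$source$context$taxon <- parse_identifier("ncbitaxon:9606"); s },
    function(s) { s$target$context$cell <- parse_identifier("cl:0000236"); s },
    function(s) { s$target$context$compartment <- parse_identifier("go:0005737"); s },
    function(s) { s$evidence$interaction_context$tissue <-
      parse_identifier("bto:0000089"); s },
    function(s) { s$source$biological_type <- parse_identifier("mi:0326"); s }
  )
  s <- base
  for (f in enrich) {
    s <- f(s)
    expect_equal(nrow(error_findings(validate(s, CFG))), n0)
  }
})

test_that("the minimum profile suppresses warnings and info", {
  s <- minimal_valid_statement()
  s$relation <- causal_relation("ro:0002410", mechanism = "mi:2247")
  strict <- validate(s, CFG)
  expect_true(any(strict$severity != "ERROR"))
  minimal <- validate(s, rule_config(profile = "minimum"))
  expect_true(all(minimal$severity == "ERROR"))
})

test_that("the activity/mechanism equivalence table is bijective", {
  expect_equal(curie(equivalent_mechanism("go:0016301")), "mi:0217")
  expect_equal(curie(equivalent_activity("mi:0217")), "go:0016301")
  expect_null(equivalent_mechanism("go:0003700"))
  map <- default_equivalence_map()
  for (i in seq_len(nrow(map))) {
    expect_equal(curie(equivalent_activity(map$mechanism[i])),
                 map$activity[i])
  }
})

test_that("compliance levels summarize reports as designed", {
  expect_equal(compliance_level(validate(minimal_valid_statement(), CFG)),
               "context_enriched")

  s <- minimal_valid_statement()
  s$source$context <- entity_context()
  s$relation <- causal_relation("ro:0002629")  # no activity, no mechanism
  expect_equal(compliance_level(validate(s, CFG)), "minimum")

  s$evidence <- evidence_set(evidence_types = "eco:0000204")
  expect_equal(compliance_level(validate(s, CFG)), "non_compliant")
})

test_that("tidy, glance and autoplot work on reports", {
  r <- validate(worked_example(), CFG)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  g <- glance(r)
  expect_equal(g$n_error, 0L)
  expect_equal(g$compliance, "context_enriched")
  expect_equal(g$statement_key, statement_key(worked_example()))
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
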