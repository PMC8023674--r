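test_that("identifier parsing splits on the first colon and normalizes case", {
  id <- parse_identifier("GO:0016301")
  expect_equal(id$prefix, "go")
  expect_equal(id$local_id, "0016301")

  doi <- parse_identifier("doi:10.1093/x:y")
  expect_equal(doi$prefix, "doi")
  expect_equal(doi$local_id, "10.1093/x:y")

  expect_error(parse_identifier("nocolon"), class = "mi2cast_parse_error")
  expect_error(parse_identifier(":x"), class = "mi2cast_parse_error")
  expect_error(parse_identifier("x:"), class = "mi2cast_parse_error")
})

tolower_prefix <- function(c) {
  pos <- regexpr(":", c, fixed = TRUE)
  paste0(tolower(substr(c, 1, pos - 1)), substr(c, pos, nchar(c)))
}

test_that("CURIE rendering round-trips through parsing", {
  for (c in c("uniprotkb:P07948-2", "doi:10.1093/a:b:c",
              "cellosaurus:CVCL_0030", "mod:00048")) {
    expect_identical(curie(parse_identifier(c)), tolower_prefix(c))
  }
})

test_that("constructors reject invariant violations with the offending field", {
  e <- tryCatch(identifier("GO!", "1"), condition = identity)
  expect_s3_class(e, "mi2cast_invalid")
  expect_equal(e$field, "prefix")

  e <- tryCatch(identifier("go", "00 1"), condition = identity)
  expect_equal(e$field, "local_id")

  # position without residue is uninterpretable
  e <- tryCatch(modification_state("mod:00048", position = 5),
                condition = identity)
  expect_s3_class(e, "mi2cast_invalid")
  expect_equal(e$field, "residue")
  expect_error(modification_state("mod:00048", residue = "chebi:17895",
                                  position = 0),
               class = "mi2cast_invalid")

  # components imply a biological type, and must be distinct
  e <- tryCatch(bio_entity("complexportal:CPX-1",
                           components = c("uniprotkb:P07948")),
                condition = identity)
  expect_equal(e$field, "biological_type")
  e <- tryCatch(bio_entity("complexportal:CPX-1", biological_type = "mi:0314",
                           components = c("uniprotkb:P07948",
                                          "uniprotkb:P07948")),
                condition = identity)
  expect_equal(e$field, "components")

  # references restricted to the literature namespaces, pairwise distinct
  expect_error(evidence_set(references = "go:0000001"),
               class = "mi2cast_invalid")
  expect_error(evidence_set(references = c("pubmed:1", "pubmed:1")),
               class = "mi2cast_invalid")

  # relation terms come from the causal vocabularies
  expect_error(causal_relation("go:0008150"), class = "mi2cast_invalid")
})

test_that("statement keys are deterministic and context-sensitive", {
  base <- worked_example()
  expect_identical(statement_key(base), statement_key(worked_example()))

  # a different cell type is a different statement instance
  other <- worked_example()
  other$target$context$cell <- parse_identifier("cl:0000057")
  expect_false(statement_key(other) == statement_key(base))

  # the supporting papers are not part of the identity
  k1 <- statement_key(causal_statement(
    bio_entity("uniprotkb:P07948"), bio_entity("uniprotkb:P29350"),
    causal_relation("ro:0002629"),
    evidence_set(references = c("pubmed:1", "pubmed:2"))))
  k2 <- statement_key(causal_statement(
    bio_entity("uniprotkb:P07948"), bio_entity("uniprotkb:P29350"),
    causal_relation("ro:0002629"),
    evidence_set(references = c("pubmed:2", "pubmed:1"))))
  k3 <- statement_key(causal_statement(
    bio_entity("uniprotkb:P07948"), bio_entity("uniprotkb:P29350"),
    causal_relation("ro:0002629"),
    evidence_set(references = "pubmed:99")))
  expect_identical(k1, k2)
  expect_identical(k1, k3)
})

test_that("statement keys survive serialization round-trips", {
  g <- generate_statements(25, seed = 11)
  keys <- vapply(g$statements, statement_key, character(1))
  back <- read_statements_json(write_statements_json(g$statements))
  expect_identical(vapply(back, statement_key, character(1)), keys)
})

test_that("list-valued fields are stored in canonical order", {
  as_source_list <- function(e) {
    statement_to_list(causal_statement(e, bio_entity("uniprotkb:P1")))$source
  }
  e1 <- bio_entity("complexportal:CPX-1", biological_type = "mi:0314",
                   components = c("uniprotkb:P2", "uniprotkb:P1"))
  e2 <- bio_entity("complexportal:CPX-1", biological_type = "mi:0314",
                   components = c("uniprotkb:P1", "uniprotkb:P2"))
  expect_identical(as_source_list(e1), as_source_list(e2))
})
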