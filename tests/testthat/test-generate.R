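test_that("generation is deterministic for a fixed seed and honours n", {
  a <- generate_statements(15, rates = c(R3.1 = 0.3), seed = 7)
  b <- generate_statements(15, rates = c(R3.1 = 0.3), seed = 7)
  expect_identical(write_statements_json(a$statements),
                   write_statements_json(b$statements))
  expect_identical(a$ground_truth, b$ground_truth)

  z <- generate_statements(0, seed = 1)
  expect_length(z$statements, 0L)
  expect_equal(nrow(z$ground_truth), 0L)
})

test_that("statements generated with zero rates validate clean", {
  g <- generate_statements(50, seed = 1)
  expect_equal(nrow(g$ground_truth), 0L)
  f <- validate_corpus(g$statements, CFG)
  expect_equal(nrow(f[f$severity %in% c("ERROR", "WARNING"), ]), 0L)
})

test_that("violation rates are validated", {
  expect_error(generate_statements(5, rates = c(R3.1 = 1.5)), "rate")
  expect_error(generate_statements(5, rates = c(R9 = 0.1)), "unknown")
})

test_that("injected violations are reproduced exactly by the validator", {
  rates <- c(R1.entity = 0.15, R2.relation = 0.15, R3.1 = 0.15,
             R4.3 = 0.15, X.syntax = 0.15)
  g <- generate_statements(150, rates = rates, seed = 13)
  expect_gt(nrow(g$ground_truth), 0L)
  f <- validate_corpus(g$statements, CFG)
  got <- f[f$severity %in% c("ERROR", "WARNING"),
           c("statement", "rule_id", "path")]
  got <- got[order(got$statement, got$path, got$rule_id), ]
  truth <- g$ground_truth[order(g$ground_truth$statement,
                                g$ground_truth$path,
                                g$ground_truth$rule_id), ]
  expect_equal(as.data.frame(got), as.data.frame(truth),
               ignore_attr = TRUE)
})

test_that("per-rule injection counts track the Bernoulli draws", {
  g <- generate_statements(400, rates = c(R3.1 = 0.25), seed = 31)
  k <- sum(g$ground_truth$rule_id == "R3.1.reference")
  # 3-sigma band around n * p for a binomial(400, 0.25)
  expect_gt(k, 400 * 0.25 - 3 * sqrt(400 * 0.25 * 0.75))
  expect_lt(k, 400 * 0.25 + 3 * sqrt(400 * 0.25 * 0.75))
})

test_that("the worked example matches its published annotation", {
  we <- worked_example()
  expect_equal(curie(we$source$identifier), "uniprotkb:P07948")
  expect_equal(curie(we$target$identifier), "uniprotkb:P29350")
  expect_equal(curie(we$relation$mechanism), "mi:0217")
  expect_equal(we$relation$target_modification_effect$position, 564L)
  expect_equal(curie(we$relation$target_modification_effect$modification_type),
               "mod:00048")
  expect_equal(curie(we$source$context$biological_activity), "go:0016301")
  # identity key frozen: regressions in canonicalization would change it
  expect_equal(statement_key(we), "8224b517ebd3d5d17b490c107c0133b2")
})
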