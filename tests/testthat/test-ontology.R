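test_that("OBO loading builds the expected index", {
  idx <- load_obo(c(
    "[Term]", "id: A:1", "name: root", "",
    "[Term]", "id: A:2", "name: mid", "is_a: A:1 ! root", "",
    "[Term]", "id: A:3", "name: leaf", "is_a: A:2"
  ))
  expect_equal(nrow(idx$terms), 3L)
  expect_equal(sum(lengths(idx$parents) == 0L), 1L)
  expect_setequal(idx$ancestors[["a:3"]], c("a:3", "a:2", "a:1"))

  expect_equal(nrow(load_obo(character())$terms), 0L)

  expect_error(
    load_obo(c("[Term]", "id: A:1", "is_a: A:2", "",
               "[Term]", "id: A:2", "is_a: A:1")),
    regexp = "cycle", class = "mi2cast_parse_error")
  expect_error(
    load_obo(c("[Term]", "id: A:1", "is_a: A:9")),
    regexp = "not defined", class = "mi2cast_parse_error")
})

test_that("obsolete terms are retained but flagged", {
  idx <- load_obo(c("[Term]", "id: A:1", "",
                    "[Term]", "id: A:2", "is_a: A:1",
                    "is_obsolete: true"))
  expect_true(idx$terms$obsolete[idx$terms$id == "a:2"])
  expect_equal(in_branch("a:2", "a:1", idx), "yes")
})

test_that("branch membership handles reflexivity, absence and fixtures", {
  expect_equal(in_branch("mi:0217", "mi:0407", ONT), "yes")
  expect_equal(in_branch("mi:0217", "mi:0217", ONT), "yes")  # reflexive
  expect_equal(in_branch("mi:0217", "eco:0000000", ONT), "no")
  expect_equal(in_branch("nosuch:1", "mi:0407", ONT), "unknown")
  expect_equal(in_branch("mi:0217", "nosuch:1", ONT), "unknown")
  expect_equal(in_branch(NULL, "mi:0407", ONT), "unknown")
})

test_that("branch membership matches a brute-force DFS on a random DAG", {
  dag <- random_dag(200, seed = 42)
  idx <- load_obo(dag$obo)
  # exhaustive over all term x root pairs
  for (root in dag$ids) {
    expected <- vapply(dag$ids, dfs_reaches, logical(1), root = root,
                       parents = dag$parents)
    got <- vapply(dag$ids, function(t) in_branch(t, root, idx),
                  character(1)) == "yes"
    expect_identical(unname(got), unname(expected), label = root)
  }
})

test_that("membership is monotone along is_a edges", {
  dag <- random_dag(120, seed = 9)
  idx <- load_obo(dag$obo)
  roots <- sample(dag$ids, 10)
  for (root in roots) {
    for (t in dag$ids) {
      if (in_branch(t, root, idx) == "yes") {
        children <- dag$ids[vapply(dag$parents, function(p) t %in% p,
                                   logical(1))]
        for (ch in children) {
          expect_equal(in_branch(ch, root, idx), "yes")
        }
      }
    }
  }
})

test_that("most-specific usage flags exactly the branch roots", {
  roots <- c("ro:0002410", "mi:2233")
  expect_false(is_most_specific_usage("ro:0002410", roots, ONT))
  expect_false(is_most_specific_usage("mi:2233", roots, ONT))
  expect_true(is_most_specific_usage("ro:0002629", roots, ONT))
  expect_true(is_most_specific_usage("ro:0002213", roots, ONT))  # mid-level
})

test_that("merging ontologies rejects colliding term ids", {
  a <- load_obo(c("[Term]", "id: A:1"))
  expect_error(merge_ontologies(a, a), class = "mi2cast_parse_error")
})
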