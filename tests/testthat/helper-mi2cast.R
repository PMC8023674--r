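# shared fixtures: one config reused across files (ontology/registry load once)
CFG <- rule_config()
ONT <- CFG$ontology

# random is_a DAG: term i may only point at earlier terms, so acyclic by
# construction; returns the parent map and the OBO text rendering it
random_dag <- function(n, seed, max_parents = 3L) {
  withr::with_seed(seed, {
    ids <- sprintf("tst:%04d", seq_len(n))
    parents <- lapply(seq_len(n), function(i) {
      if (i == 1L) return(character())
      k <- sample(0:min(max_parents, i - 1L), 1L)
      if (k == 0L) character() else sample(ids[seq_len(i - 1L)], k)
    })
    names(parents) <- ids
    obo <- unlist(lapply(seq_len(n), function(i) {
      c("[Term]",
        paste0("id: ", ids[i]),
        paste0("name: term ", i),
        if (length(parents[[i]]) > 0L) paste0("is_a: ", parents[[i]]),
        "")
    }))
    list(ids = ids, parents = parents, obo = obo)
  })
}

# independent brute-force oracle: plain recursive DFS over the raw parent map
dfs_reaches <- function(term, root, parents) {
  if (term == root) return(TRUE)
  for (p in parents[[term]]) {
    if (dfs_reaches(p, root, parents)) return(TRUE)
  }
  FALSE
}

stmt_canonical <- function(s) statement_to_list(s)

minimal_valid_statement <- function() {
  causal_statement(
    source = bio_entity("uniprotkb:P07948",
                        context = entity_context(
                          biological_activity = "go:0016301")),
    target = bio_entity("uniprotkb:P29350"),
    relation = causal_relation("ro:0002629", mechanism = "mi:2247"),
    evidence = evidence_set(references = "pubmed:1234567",
                            evidence_types = "eco:0000204")
  )
}

error_findings <- function(report) {
  tibble::as_tibble(report)[report$severity == "ERROR", , drop = FALSE]
}
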