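#' Regulatory sign of a causal relation term
#'
#' Classifies a relation term as positive, negative or unsigned by its
#' position under the positive-regulation and negative-regulation
#' sub-branches of the causal vocabularies (RO:0002213/RO:0002212 and the
#' PSI-MI up-/down-regulates terms). Terms the index cannot place are
#' unsigned.
#'
#' @param term Relation term [identifier()] or CURIE, or `NULL`.
#' @param ontology A `mi2cast_ontology`.
#' @param branches Branch configuration, see [default_branches()].
#' @return `"positive"`, `"negative"` or `"unsigned"`.
#' @export
relation_sign <- function(term, ontology = default_ontology(),
                          branches = default_branches()) {
  if (is.null(term)) return("unsigned")
  if (in_branch(term, branches$relation_positive, ontology) == "yes") {
    return("positive")
  }
  if (in_branch(term, branches$relation_negative, ontology) == "yes") {
    return("negative")
  }
  "unsigned"
}

#' Export statements as SIF triples
#'
#' The Simple Interaction Format holds only `source <token> target`, the
#' most reduced causal-statement form ('A activates B', 'A -> B'). Export is
#' lossy by design — context and evidence are dropped and there is no
#' reader. One line is emitted per statement; the relation token encodes the
#' regulatory sign.
#'
#' @param stmts A list of [causal_statement()] records.
#' @param path Optional output file.
#' @param ontology,branches Passed to [relation_sign()].
#' @param tokens Named map from sign to SIF relation token.
#' @return A character vector of lines, one per statement.
#' @examples
#' export_sif(list(worked_example()))
#' @export
export_sif <- function(stmts, path = NULL, ontology = default_ontology(),
                       branches = default_branches(),
                       tokens = c(positive = "->", negative = "-|",
                                  unsigned = "--")) {
  lines <- vapply(stmts, function(s) {
    lbl <- function(id) if (is.null(id)) "-" else curie(id)
    sign <- relation_sign(s$relation$relation_term, ontology, branches)
    paste(lbl(s$source$identifier), tokens[[sign]],
          lbl(s$target$identifier))
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
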