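# mi2castr

Curation quality control for **causal molecular interaction statements** —
the directed, signed records ("A, having kinase activity, up-regulates B")
that signed regulatory networks are built from. `mi2castr` implements the
MI2CAST minimum-information checklist as executable software, for curators
and database maintainers who need to lint causal statements, and for
modellers who need to exchange them between resources.

The checklist's four rules become a rule engine:

1. **Entities** — source and target must carry reference identifiers
   (CURIEs such as `uniprotkb:P07948`); complexes/families must list
   their components.
2. **Causal relation** — a term from the 'causally related to' branch of
   the Relation Ontology (RO:0002410) or the PSI-MI 'causal statement'
   branch (MI:2233); bare branch roots are flagged as maximally generic.
3. **Provenance and evidence** — at least one PubMed/DOI reference and an
   ECO evidence type; experimental evidence should record setup terms
   (ECO / MI:0346 / OBI).
4. **Context** — activity or mechanism (GO-MF / ChEBI role / SO;
   MI:2245 / MI:0190 / GO-BP), biological type (MI:0313) whenever the
   namespace implies none, resulting modification of modifying mechanisms,
   numeric NCBI taxa, and tissue/cell/compartment terms from their
   branches.

"must" ⇒ `ERROR`, "should" ⇒ `WARNING`, advisory ⇒ `INFO`; reports are
deterministic tibbles and `compliance_level()` grades each statement
`non_compliant` / `minimum` / `context_enriched`. Branch membership is
reflexive-transitive `is_a` reachability over OBO subsets (`load_obo()`,
`in_branch()`); identifier syntax is checked against a shipped, editable
namespace registry — offline, syntax-only, never a remote lookup.
Statements serialize losslessly to canonical JSON and PSI-MITAB 2.8
(whose trailing causal columns were designed for exactly this data), and
lossily to SIF (`A -> B` / `A -| B`). A seeded generator produces valid
corpora and corpora with precisely recorded rule violations for
benchmarking.

## Worked example

The classic fully annotated statement — the kinase LYN phosphorylates the
phosphatase PTPN6 at Tyr-564, stimulating its activity — ships as
`worked_example()`:

```r
library(mi2castr)

we <- worked_example()
we
#> <mi2cast_statement>
#>   uniprotkb:P07948 --[ro:0002629]--> uniprotkb:P29350
#>   mechanism: mi:0217
#>   references: pubmed:10068674

glance(validate(we))
#> # A tibble: 1 × 5
#>   statement_key                    n_error n_warning n_info compliance
#>   <chr>                              <int>     <int>  <int> <chr>
#> 1 8224b517ebd3d5d17b490c107c0133b2       0         0      2 context_enriched
```

Zero errors and zero warnings: the statement satisfies all four rules (the
two INFO lines are the reviewed-accession reminders for the UniProt
entities). Strip its evidence and the engine pinpoints the violated musts:

```r
incomplete <- we
incomplete$evidence <- evidence_set()
tidy(validate(incomplete, rule_config(profile = "minimum")))
#> # A tibble: 2 × 5
#>   rule_id        severity path                    message                  kind
#>   <chr>          <chr>    <chr>                   <chr>                    <chr>
#> 1 R3.2.evidence  ERROR    evidence.evidence_types no ECO evidence type is… abse…
#> 2 R3.1.reference ERROR    evidence.references     no supporting reference… abse…

export_sif(list(we))
#> [1] "uniprotkb:P07948 -> uniprotkb:P29350"
```

Batch workflows chain with the pipe: `read_statements_json(path) |>
validate_corpus() |> plot_findings()`. A thin CLI wraps the same
functions: `exec/mi2cast validate|convert|generate` with `--in`, `--out`,
`--in-format`/`--out-format` (`json`, `mitab28`, `sif`), `--profile`,
`--seed`, `--n`; exit status 0 (clean), 1 (ERROR findings), 2 (I/O or
usage failure).

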