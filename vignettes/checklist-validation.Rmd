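---
title: "Validating causal molecular interaction statements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating causal molecular interaction statements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mi2castr)
```

## The problem

A *causal statement* records that the action of a source biomolecule
influences the activity or quantity of a target biomolecule — "the kinase
activity of LYN increases the phosphatase activity of PTPN6". Such
statements are the building blocks of signed regulatory networks, and they
are curated from the literature by many databases using many conventions.
Whether a statement can be reused depends on its metadata: which exact
entities, which regulatory sign, under which evidence, in which taxon, cell
and compartment. The MI2CAST checklist standardizes that metadata as four
rules: (1) identified source and target entities, (2) a causal relation
from a controlled vocabulary, (3) provenance and ECO evidence, and (4)
contextual detail — activity or mechanism, biological type, modification
state, taxon and location. `mi2castr` implements the checklist as a typed
data model, a rule engine that grades statements, interoperable
serializations (canonical JSON, PSI-MITAB 2.8, SIF), and a generator of
benchmark corpora.

## The data model

A `causal_statement()` is source + target (`bio_entity()`), a
`causal_relation()` and an `evidence_set()`. Every identifier is a CURIE
(`uniprotkb:P07948`, `go:0016301`); the first colon separates the
lower-case namespace from the case-preserving accession, so DOIs with
embedded colons parse correctly. Context (`entity_context()`) can sit on
either entity *and* on the interaction (in the evidence record); the model
stores both levels and never copies between them, because the checklist
explicitly allows annotation at either level and the two are not
interchangeable (a heterologous assay has different entity taxa and no
single interaction taxon).

Deliberate structural permissiveness: an entity with a missing identifier
or a relation with no term still *constructs*, because the validator must
be able to lint incomplete records; hard invariants are reserved for
combinations that are uninterpretable in any record (a modification
position without a residue, duplicate components, a reference outside
pubmed/doi). Sequence positions are 1-based, the protein-residue numbering
convention ("Tyr-564" denotes the 564th residue). Isoforms are carried in
the accession itself (`uniprotkb:P29350-2`), not as a separate field.

Each statement has a `statement_key()`: a hash over all entity, relation
and context fields with list fields sorted and the reference list
*excluded*. Two records that differ only in supporting papers are the same
interaction instance (and their trustworthiness is deliberately not scored
by counting references); two records that differ in any context field —
say the cell type — are distinct instances, as the checklist requires.

## Severity semantics

The engine maps the checklist's modal verbs onto severities: **must** ⇒
`ERROR`, including the conditional musts that live inside recommended
rules (a complex without components, a fallback-namespace entity without a
biological type); **should/recommended** ⇒ `WARNING`; advisory output ⇒
`INFO` (unverifiable terms when an ontology is not loaded, the
Swiss-Prot-preference reminder that syntax cannot decide, and
activity↔mechanism equivalence suggestions). INFO findings are never
violations — they either flag what could not be checked or recommend
style — which is why benchmark comparisons against generator ground truth
are made at ERROR+WARNING level. Reports are tibbles sorted by
`(path, rule_id)` with C-locale ordering, so a report is a pure,
reproducible function of statement and configuration. `compliance_level()`
collapses a report to `non_compliant` (any ERROR), `minimum` (essentials
present, Rule 4 context absent) or `context_enriched`.

Two consistency checks are deliberately *not* performed, because the
checklist provides no decision procedure: direct-vs-indirect coherence
between a relation term and a mechanism term, and agreement between an
interaction-level taxon and the entity taxa. Tissue-ontology choice by
kingdom (plant/fungal vs metazoan) is likewise not policed: no plant or
fungal fixture is bundled, so the mismatch is never decidable here.

## Ontology branch checks

Every "term must come from branch X" rule reduces to reflexive-transitive
`is_a` reachability. `load_obo()` reads a small OBO subset ([Term] stanzas;
`id`, `name`, `is_a`, `is_obsolete`), rejects cycles and dangling parents
at load, and precomputes ancestor sets, so `in_branch()` is a constant-time
lookup. Only `is_a` edges count — all the checklist's branch constraints
are subsumption branches — and obsolete terms keep their membership but
draw a dedicated warning. A term (or branch root) absent from the loaded
index yields `"unknown"` and an INFO finding rather than an error: the
checklist must remain usable without full ontology downloads.

"Use the lowest possible level term" is context-dependent and not
decidable from the graph, so `is_most_specific_usage()` is a stated weak
proxy: only a term that *is* a branch root (e.g. a bare 'causally related
to') is flagged as maximally generic.

The bundled fixtures are hand-written miniature subsets (≤ 30 terms each)
containing every term id the checklist names, with plausible `is_a` paths;
they are test scaffolding, not ontology releases, and the Cellosaurus
stand-in (which has no real hierarchy) hangs cell lines under an invented
synthetic root.

## The namespace registry

`default_registry()` ships the entity-class/database table as an editable
TSV: accession regular expression, implied interactor type, applicable
entity classes and primary/alternative rank per namespace. Checking is
syntax-only — accession existence is never verified remotely, keeping every
run offline-reproducible. The Swiss-Prot-vs-TrEMBL preference is not
syntax-decidable and is therefore surfaced as a per-identifier INFO
reminder rather than a pass/fail check.

## Serialization choices

*JSON* is the canonical lossless dialect: versioned header, fixed key
order, empties omitted, list fields pre-sorted — writers are
byte-deterministic and `read(write(x))` is the identity on the full model.

*PSI-MITAB 2.8* holds the checklist's core natively: interactor columns,
biological-effect columns (43/44) for entity activities, the
causal-regulatory-mechanism (45) and causal-statement (46) columns, taxid
columns, feature columns for prior modifications, the publication column.
Fields with no MITAB home — components, tissue/cell/compartment, setup
terms, ECO evidence types, the resulting target modification — travel in
the annotation columns under a reserved `mi2cast:"key=value"` tag, which
keeps the round trip exact without violating the column semantics. Where
the standard leaves the evidence placement open, ECO terms live in the
tags and an MI detection-method term is additionally emitted in column 7
when a shipped ECO→MI cross-reference exists.

*SIF* is export-only and lossy by design: one
`source <token> target` line per statement, with the token chosen by the
relation term's position under the positive/negative regulation
sub-branches (`->`, `-|`, unsigned `--`).

For translocation statements the entity keeps its *origin* compartment;
the destination is conveyed by a mechanism term such as 'import into
nucleus', checked only as GO-BP branch membership.

## The synthetic corpus generator

`generate_statements(n, rates, seed)` emulates a curated corpus: entities
drawn from UniProtKB (random syntactically valid accessions), NCBI-gene
fallbacks with explicit protein types, Complex Portal complexes with
component lists, and ChEBI chemicals with role-branch activities; specific
signed relation terms; mechanisms split between modification reactions
(with a matching resulting phospho-residue on the target) and
transcriptional/transport regulation; PubMed references; ECO experimental
evidence with an overexpressed-source setup term; taxa, compartments,
tissues and cells sprinkled at realistic frequencies. Violations are
injected per rule as independent Bernoulli draws from one private RNG
stream, each a minimal single-field corruption, and recorded exactly in a
ground-truth table. A statement generated with all rates zero validates
with no ERROR or WARNING — which is what makes exact
validator-vs-ground-truth equivalence a meaningful benchmark. The one
interaction between corruptions (a dropped target identifier hides a
dropped target type) is resolved by precedence and documented in
`?generate_statements`.

What the generator does **not** emulate: real accession populations,
degree distributions of regulatory networks, correlated missingness of
context fields, or free-text curation noise. Passing the equivalence
benchmark therefore demonstrates that the engine detects exactly the
seeded violation classes, not that it catches every defect arising in
real curated data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use corpora of 1000 statements
for the validator benchmark and the round-trip checks, and an exhaustive
200-term random DAG (all 40 000 term×root pairs against a brute-force DFS
oracle) for branch membership — sizes chosen so the full suite re-runs in
about a minute while still exercising every rule path and collision case.
Ties in report order are broken by the `(path, rule_id)` lexicographic
sort; hashes come from a fixed canonical JSON rendering, so keys are
stable across platforms and releases (a frozen key for the worked example
guards regressions).

## Limitations

- Branch checks are only as good as the loaded ontology subsets; with the
  bundled miniatures, terms outside them report as unverifiable INFO.
- Syntax-only identifier checking cannot catch retired or mistyped but
  well-formed accessions.
- Reference-list minimality/sufficiency (Rule 3's conjunctive evidence
  sets) is not decidable from the record; only non-emptiness and
  well-formedness are enforced.
- BEL and GO-CAM serializations and live web-service queries are out of
  scope.
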