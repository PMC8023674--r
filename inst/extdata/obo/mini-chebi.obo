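format-version: 1.2
! Miniature hand-written subset of ChEBI: the role branch (CHEBI:50906) plus
! a few residues/chemicals. Test scaffolding, not an ontology release.

[Term]
id: CHEBI:24431
name: chemical entity

[Term]
id: CHEBI:50906
name: role

[Term]
id: CHEBI:35223
name: catalyst
is_a: CHEBI:50906

[Term]
id: CHEBI:23888
name: drug
is_a: CHEBI:50906

[Term]
id: CHEBI:25212
name: metabolite
is_a: CHEBI:50906

[Term]
id: CHEBI:17895
name: L-tyrosine
is_a: CHEBI:24431

[Term]
id: CHEBI:17115
name: L-serine
is_a: CHEBI:24431

[Term]
id: CHEBI:16857
name: L-threonine
is_a: CHEBI:24431

[Term]
id: CHEBI:29101
name: sodium(1+)
is_a: CHEBI:24431
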