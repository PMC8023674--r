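format-version: 1.2
! Miniature hand-written subset of the Cell Ontology.
! Test scaffolding, not an ontology release.

[Term]
id: CL:0000000
name: cell

[Term]
id: CL:0000236
name: B cell
is_a: CL:0000000

[Term]
id: CL:0000057
name: fibroblast
is_a: CL:0000000
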