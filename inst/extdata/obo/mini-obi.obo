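format-version: 1.2
! Miniature hand-written subset of the Ontology for Biomedical Investigations.
! Test scaffolding, not an ontology release.

[Term]
id: OBI:0000070
name: assay

[Term]
id: OBI:0001146
name: binding assay
is_a: OBI:0000070
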