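format-version: 1.2
! Miniature hand-written subset of Uberon.
! Test scaffolding, not an ontology release.

[Term]
id: UBERON:0000061
name: anatomical structure

[Term]
id: UBERON:0002107
name: liver
is_a: UBERON:0000061

[Term]
id: UBERON:0002106
name: spleen
is_a: UBERON:0000061
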