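format-version: 1.2
! Miniature hand-written subset of the BRENDA tissue ontology.
! Test scaffolding, not an ontology release.

[Term]
id: BTO:0000000
name: tissues, cell types and enzyme sources

[Term]
id: BTO:0000089
name: blood
is_a: BTO:0000000

[Term]
id: BTO:0000759
name: liver
is_a: BTO:0000000
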