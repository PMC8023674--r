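format-version: 1.2
! Miniature hand-written subset of the PSI-MI controlled vocabulary.
! Cited term ids are real; filler terms added for plausible is_a paths are
! illustrative. Test scaffolding, not an ontology release.

[Term]
id: MI:0000
name: molecular interaction

[Term]
id: MI:2233
name: causal statement
is_a: MI:0000

[Term]
id: MI:2234
name: up-regulates
is_a: MI:2233

[Term]
id: MI:2236
name: up-regulates activity
is_a: MI:2234

[Term]
id: MI:2240
name: down-regulates
is_a: MI:2233

[Term]
id: MI:2241
name: down-regulates activity
is_a: MI:2240

[Term]
id: MI:0313
name: interactor type
is_a: MI:0000

[Term]
id: MI:0326
name: protein
is_a: MI:0313

[Term]
id: MI:0328
name: small molecule
is_a: MI:0313

[Term]
id: MI:0250
name: gene
is_a: MI:0313

[Term]
id: MI:0320
name: ribonucleic acid
is_a: MI:0313

[Term]
id: MI:0314
name: complex
is_a: MI:0313

[Term]
id: MI:1304
name: entity family
is_a: MI:0313

[Term]
id: MI:0346
name: experimental preparation
is_a: MI:0000

[Term]
id: MI:0506
name: over expressed level
is_a: MI:0346

[Term]
id: MI:0331
name: engineered
is_a: MI:0346

[Term]
id: MI:2245
name: causal regulatory mechanism
is_a: MI:0000

[Term]
id: MI:2247
name: transcriptional regulation
is_a: MI:2245

[Term]
id: MI:2249
name: post transcriptional regulation
is_a: MI:2245

[Term]
id: MI:0190
name: interaction type
is_a: MI:0000

[Term]
id: MI:0407
name: direct interaction
is_a: MI:0190

[Term]
id: MI:0217
name: phosphorylation reaction
is_a: MI:0407

[Term]
id: MI:0203
name: dephosphorylation reaction
is_a: MI:0407

[Term]
id: MI:0220
name: ubiquitination reaction
is_a: MI:0407

[Term]
id: MI:0001
name: interaction detection method
is_a: MI:0000

[Term]
id: MI:0018
name: two hybrid
is_a: MI:0001

[Term]
id: MI:0999
name: retired example term
is_a: MI:0000
is_obsolete: true
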