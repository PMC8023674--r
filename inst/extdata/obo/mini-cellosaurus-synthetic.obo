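format-version: 1.2
! SYNTHETIC stand-in for Cellosaurus cell-line accessions. Cellosaurus is not
! an is_a hierarchy, so this fixture invents a single synthetic root
! (cellosaurus:CVCL_0000) under which cell-line terms hang for branch checks.
! Test scaffolding only.

[Term]
id: cellosaurus:CVCL_0000
name: cell line (synthetic root)

[Term]
id: cellosaurus:CVCL_0030
name: HeLa
is_a: cellosaurus:CVCL_0000

[Term]
id: cellosaurus:CVCL_0004
name: K-562
is_a: cellosaurus:CVCL_0000
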