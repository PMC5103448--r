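# Default diagnostic-feature catalog for the ancestral lophotrochozoan
# homeobox toolkit: 11 Hox paralog groups and 3 ParaHox genes.
#
# Features carry coordinates in the canonical homeodomain frame
# (HD_POS 1-60; C_FLANK offsets +1,+2,... start after position 60;
# N_FLANK offsets -1,-2,... precede position 1).  A feature with an empty
# pattern and weight 0 is a placeholder: the literature localizes it but
# does not print its residues, so it is inert for scoring until a user
# fills it in (e.g. from discover_signatures() on their own alignment).
groups:
- name: Hox1
  class: hox
  features:
  - id: hox1_hd_nonbasic_2_3
    region: HD_POS
    positions: [2, 3]
    predicate: non_basic
    weight: 1.0
    scope: bilaterian
  - id: hox1_hd_motif_6_8
    region: HD_POS
    positions: [6, 7, 8]
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: conserved motif, residues not printed; placeholder
  - id: hox1_hd_29
    region: HD_POS
    positions: [29]
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: unique single-residue signature; placeholder
  - id: hox1_hd_56
    region: HD_POS
    positions: [56]
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: unique single-residue signature; placeholder
  - id: hox1_cflank_1_2
    region: C_FLANK
    offset: 1
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: conserved motif at C-flank offsets +1/+2; placeholder
- name: Hox2
  class: hox
  features:
  - id: hox2_hd_flanked_basic_4
    region: HD_POS
    positions: [4]
    predicate: flanked_by_basic
    weight: 1.0
    scope: bilaterian
  - id: hox2_hd_2
    region: HD_POS
    positions: [2]
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: placeholder
  - id: hox2_hd_24
    region: HD_POS
    positions: [24]
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: placeholder
  - id: hox2_hd_58_59
    region: HD_POS
    positions: [58, 59]
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: placeholder
- name: Hox3
  class: hox
  features:
  - id: hox3_hd_flanked_basic_4
    region: HD_POS
    positions: [4]
    predicate: flanked_by_basic
    weight: 1.0
    scope: bilaterian
  - id: hox3_hd_al_36_37
    region: HD_POS
    positions: [36, 37]
    pattern: AL
    weight: 1.0
    scope: lophotrochozoan
  - id: hox3_hd_14
    region: HD_POS
    positions: [14]
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: conserved bilaterian residue; placeholder
- name: Hox4
  class: hox
  features:
  - id: hox4_nflank_ypwm
    region: N_FLANK
    pattern: YPWM
    weight: 1.0
    scope: bilaterian
  - id: hox4_cflank_lpntk
    region: C_FLANK
    pattern: LPNTK
    weight: 1.0
    scope: bilaterian
- name: Hox5
  class: hox
  features:
  - id: hox5_nflank_ypwm
    region: N_FLANK
    pattern: YPWM
    weight: 1.0
    scope: bilaterian
  - id: hox5_cflank_hiaknm
    region: C_FLANK
    offset: 1
    pattern: HIAKNM
    weight: 1.0
    scope: molluscan
- name: Lox5
  class: hox
  features:
  - id: lox5_parapeptide
    region: C_FLANK
    pattern: ''
    weight: 0.0
    scope: lophotrochozoan
    note: Lox5 parapeptide; placeholder
- name: Antp
  class: hox
  features:
  - id: antp_nflank_hox_pbc
    region: N_FLANK
    pattern: ''
    weight: 0.0
    scope: bilaterian
    note: Hox-PBC interaction region right before the homeodomain; placeholder
- name: Lox4
  class: hox
  features:
  - id: lox4_parapeptide
    region: C_FLANK
    pattern: ''
    weight: 0.0
    scope: lophotrochozoan
    note: Ubd-A parapeptide; placeholder
- name: Lox2
  class: hox
  features:
  - id: lox2_parapeptide
    region: C_FLANK
    pattern: ''
    weight: 0.0
    scope: lophotrochozoan
    note: Ubd-A parapeptide; placeholder
- name: Post2
  class: hox
  features:
  - id: post2_hd_residues
    region: HD_POS
    positions: []
    pattern: ''
    weight: 0.0
    scope: lophotrochozoan
    note: posterior-class residues, not localized; placeholder
- name: Post1
  class: hox
  features:
  - id: post1_hd_residues
    region: HD_POS
    positions: []
    pattern: ''
    weight: 0.0
    scope: lophotrochozoan
    note: posterior-class residues, not localized; placeholder
- name: Gsx
  class: parahox
  features:
  - id: gsx_cflank_lrtcd
    region: C_FLANK
    pattern: LRTCD
    weight: 1.0
    scope: lophotrochozoan
- name: Xlox
  class: parahox
  features:
  - id: xlox_flank_peptides
    region: C_FLANK
    pattern: ''
    weight: 0.0
    scope: lophotrochozoan
    note: flanking-region signature peptides; placeholder
- name: Cdx
  class: parahox
  features:
  - id: cdx_flank_peptides
    region: C_FLANK
    pattern: ''
    weight: 0.0
    scope: lophotrochozoan
    note: flanking-region signature peptides; placeholder
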