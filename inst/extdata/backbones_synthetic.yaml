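# Synthetic backbone registry for MIR390-style amiRNA precursor assembly.
#
# The segment sequences below are SYNTHETIC stand-ins: they reproduce the
# published architecture of the pri-AtMIR390a / OsMIR390 precursor series
# (segment lengths, basal-stem and distal-stem-loop pairing layout, terminal
# loop sizes, 448-nt basal region, 521-nt and 89-nt totals) but are not the
# natural AtMIR390a / OsMIR390 sequences. Length invariants are enforced at
# load time, so any edit that breaks the architecture fails fast.
#
# Arm pairing conventions encoded here (see the package vignette):
#   - basal stem: 16-nt 5' arm / 17-nt 3' arm, 16 bp + one unpaired base at
#     the open end of the 3' arm (within the ~15-17 bp band)
#   - At DSL: 13 + 4 (loop) + 14 = 31 nt; Os DSL: 3 + 8 (loop) + 5 = 16 nt
#   - the last two nucleotides of each 3' DSL arm are per-construct
#     compensation positions facing guide positions 20/21 (placeholder AA
#     here; overwritten at assembly)
alphabet: rna
expected:
  pri: {dsl_length: 31, bs_region_length: 448, total_length: 521}
  OsDSL: {dsl_length: 16}
  shc: {total_length: 89, bs_stem_length: 33}
segments:
  flank5_at: UGGGGUGCACGUCCCCUAUGGGGAUUAACUGUAGACAUUACGGUCAUAUUUCGUAUUCCUAAAACCUCUUCCCUGCCGGCCAAGUCUGAGCGAUAUUCAUAUUGAUUCUUAACAACGCUCAAUGGCAGCAAGGAAGUUUUUUAGGGGGAACCAAGGAUAGAGUACCAAGCGGCCAUGAUGGCCCCGAGUUGAUUGAGGUCGUAGCAUU
  bs5_at: GCGGAUCCCAUUUGUA
  bs3_at: UACAAAUGGGAUCCGCU
  dsl5_at: GCUCUCUAUGCUU
  loop_at: GUAA
  dsl3_at: AGCAUAGAGAGCAA
  dsl5_os: GCU
  loop_os: AAUGGAAU
  dsl3_os: AGCAA
  flank3_at: CUGCUCUUACACCGACCCAUCUCAUCCGGAACGGCGGGUAACACAUUUUCUCUUCAAGACUAUGGCGCUCGCGAUCAUUGGUAAGCUGAAAUUUGCCCCUAUGCACUCUUACUUUCAUACCGGGGAAGUGUAAUAAAAACGGAGACGGAACCCCAUGAGCAAACAUUUGGCCAUAUUGGGGAGCACUGGUCCAAGUACUGGAUGCGA
backbones:
  pri:
    flank5: flank5_at
    bs5_arm: bs5_at
    dsl5_arm: dsl5_at
    loop: loop_at
    dsl3_arm: dsl3_at
    bs3_arm: bs3_at
    flank3: flank3_at
  OsDSL:
    flank5: flank5_at
    bs5_arm: bs5_at
    dsl5_arm: dsl5_os
    loop: loop_os
    dsl3_arm: dsl3_os
    bs3_arm: bs3_at
    flank3: flank3_at
  OsDS-AtL:
    flank5: flank5_at
    bs5_arm: bs5_at
    dsl5_arm: dsl5_os
    loop: loop_at
    dsl3_arm: dsl3_os
    bs3_arm: bs3_at
    flank3: flank3_at
  BS:
    bs5_arm: bs5_at
    dsl5_arm: dsl5_at
    loop: loop_at
    dsl3_arm: dsl3_at
    bs3_arm: bs3_at
  BS-OsDSL:
    bs5_arm: bs5_at
    dsl5_arm: dsl5_os
    loop: loop_os
    dsl3_arm: dsl3_os
    bs3_arm: bs3_at
derived:
  # symmetric stem deletions from a parent backbone, never stored redundantly
  AtDSL-D6: {parent: pri, stem: dsl, delete: 6}
  AtDSL-D13: {parent: pri, stem: dsl, delete: 13}
  AtDSL-D21: {parent: pri, stem: dsl, delete: 21}
  AtDSL-D25: {parent: pri, stem: dsl, delete: 25}
  OsDSL-D2: {parent: OsDSL, stem: dsl, delete: 2}
  OsDSL-D4: {parent: OsDSL, stem: dsl, delete: 4}
  OsDSL-D6: {parent: OsDSL, stem: dsl, delete: 6}
  BS-D7: {parent: BS, stem: bs, delete: 7}
  BS-D17: {parent: BS, stem: bs, delete: 17}
  BS-D23: {parent: BS, stem: bs, delete: 23}
  BS-D31: {parent: BS, stem: bs, delete: 31}
  shc: {parent: BS-OsDSL, stem: dsl, delete: 2}
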