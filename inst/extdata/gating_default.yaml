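# Default gating hierarchy: live -> CD45+CD326- leukocytes -> CD3+/- split,
# resolving 30 immune populations (23 cell types + 7 functional overlays)
# from the 26-marker panel.  Thresholds are fixed per-channel values on the
# log10 intensity scale.  Polarity semantics:
#   positive/high : x >= positive threshold
#   negative      : x <  positive threshold (complement, so splits partition)
#   low           : negative threshold <= x < positive threshold
#   expressed     : x >= negative threshold (low or high)
panel:
  markers: [CD45, CD326, CD3, CD4, CD8, CD56, CD19, CD45RA, CD197, FOXP3,
            CD25, HLA-DR, CD11c, CD123, CD68, CD14, CD11b, CD33, CD16,
            CD127, CD1c, CD141, Ki67, PD1, PDL1, CTLA4]
  scatter: [FSC, SSC]
  viability: Viability
thresholds:
  default: {negative: 1.5, positive: 2.6}
  SSC: {negative: 1.5, positive: 2.8}
nodes:
  - id: live
    parent: root
    gates:
      - {marker: Viability, polarity: negative}
  - id: leukocyte
    parent: live
    gates:
      - {marker: CD45, polarity: positive}
      - {marker: CD326, polarity: negative}
  - id: cd3pos
    parent: leukocyte
    gates:
      - {marker: CD3, polarity: positive}
  - id: nkt
    parent: cd3pos
    gates:
      - {marker: CD56, polarity: positive}
  - id: nkt_cd4
    parent: nkt
    gates:
      - {marker: CD4, polarity: positive}
      - {marker: CD8, polarity: negative}
  - id: nkt_cd8
    parent: nkt
    gates:
      - {marker: CD8, polarity: positive}
      - {marker: CD4, polarity: negative}
  - id: conv_t
    parent: cd3pos
    gates:
      - {marker: CD56, polarity: negative}
  - id: cd4_t
    parent: conv_t
    gates:
      - {marker: CD4, polarity: positive}
      - {marker: CD8, polarity: negative}
  - id: cd4_naive
    parent: cd4_t
    gates:
      - {marker: CD45RA, polarity: positive}
      - {marker: CD197, polarity: positive}
  - id: cd4_cm
    parent: cd4_t
    gates:
      - {marker: CD45RA, polarity: negative}
      - {marker: CD197, polarity: positive}
  - id: cd4_em
    parent: cd4_t
    gates:
      - {marker: CD45RA, polarity: negative}
      - {marker: CD197, polarity: negative}
  - id: cd4_emra
    parent: cd4_t
    gates:
      - {marker: CD45RA, polarity: positive}
      - {marker: CD197, polarity: negative}
  - id: treg
    parent: cd4_t
    gates:
      - {marker: FOXP3, polarity: expressed}
  - id: treg_fr1
    parent: treg
    gates:
      - {marker: CD45RA, polarity: positive}
      - {marker: FOXP3, polarity: low}
  - id: treg_fr2
    parent: treg
    gates:
      - {marker: CD45RA, polarity: negative}
      - {marker: FOXP3, polarity: high}
  - id: ctla4_etreg
    parent: treg_fr2
    gates:
      - {marker: CTLA4, polarity: positive}
  - id: treg_fr3
    parent: treg
    gates:
      - {marker: CD45RA, polarity: negative}
      - {marker: FOXP3, polarity: low}
  - id: ki67_cd4t
    parent: cd4_t
    gates:
      - {marker: Ki67, polarity: positive}
  - id: pd1_cd4t
    parent: cd4_t
    gates:
      - {marker: PD1, polarity: positive}
  - id: cd8_t
    parent: conv_t
    gates:
      - {marker: CD8, polarity: positive}
      - {marker: CD4, polarity: negative}
  - id: cd8_naive
    parent: cd8_t
    gates:
      - {marker: CD45RA, polarity: positive}
      - {marker: CD197, polarity: positive}
  - id: cd8_cm
    parent: cd8_t
    gates:
      - {marker: CD45RA, polarity: negative}
      - {marker: CD197, polarity: positive}
  - id: cd8_em
    parent: cd8_t
    gates:
      - {marker: CD45RA, polarity: negative}
      - {marker: CD197, polarity: negative}
  - id: cd8_emra
    parent: cd8_t
    gates:
      - {marker: CD45RA, polarity: positive}
      - {marker: CD197, polarity: negative}
  - id: ki67_cd8t
    parent: cd8_t
    gates:
      - {marker: Ki67, polarity: positive}
  - id: pd1_cd8t
    parent: cd8_t
    gates:
      - {marker: PD1, polarity: positive}
  - id: pdl1_cd8t
    parent: cd8_t
    gates:
      - {marker: PDL1, polarity: positive}
  - id: cd3neg
    parent: leukocyte
    gates:
      - {marker: CD3, polarity: negative}
  - id: b_cell
    parent: cd3neg
    gates:
      - {marker: CD19, polarity: positive}
  - id: nk
    parent: cd3neg
    gates:
      - {marker: CD19, polarity: negative}
      - {marker: CD56, polarity: positive}
  - id: myeloid_lin
    parent: cd3neg
    gates:
      - {marker: CD19, polarity: negative}
      - {marker: CD56, polarity: negative}
  - id: macrophage
    parent: myeloid_lin
    gates:
      - {marker: CD68, polarity: positive}
      - {marker: SSC, polarity: high}
  - id: mmdsc
    parent: myeloid_lin
    gates:
      - {marker: CD68, polarity: negative}
      - {marker: HLA-DR, polarity: low}
      - {marker: CD14, polarity: positive}
      - {marker: CD11b, polarity: positive}
      - {marker: CD33, polarity: positive}
  - id: pdl1_mmdsc
    parent: mmdsc
    gates:
      - {marker: PDL1, polarity: positive}
  - id: cd14_mono
    parent: myeloid_lin
    gates:
      - {marker: CD68, polarity: negative}
      - {marker: HLA-DR, polarity: positive}
      - {marker: CD14, polarity: positive}
  - id: cdc
    parent: myeloid_lin
    gates:
      - {marker: CD68, polarity: negative}
      - {marker: HLA-DR, polarity: positive}
      - {marker: CD14, polarity: negative}
      - {marker: CD11c, polarity: positive}
  - id: pdc
    parent: myeloid_lin
    gates:
      - {marker: CD68, polarity: negative}
      - {marker: HLA-DR, polarity: positive}
      - {marker: CD14, polarity: negative}
      - {marker: CD11c, polarity: negative}
      - {marker: CD123, polarity: positive}
populations:
  - {id: cd4_t,       node: cd4_t,       class: type}
  - {id: cd4_naive,   node: cd4_naive,   class: type, fraction_group: cd4}
  - {id: cd4_cm,      node: cd4_cm,      class: type, fraction_group: cd4}
  - {id: cd4_em,      node: cd4_em,      class: type, fraction_group: cd4}
  - {id: cd4_emra,    node: cd4_emra,    class: type, fraction_group: cd4}
  - {id: treg,        node: treg,        class: type, fraction_group: cd4}
  - {id: treg_fr1,    node: treg_fr1,    class: type, fraction_group: cd4}
  - {id: treg_fr2,    node: treg_fr2,    class: type, fraction_group: cd4}
  - {id: treg_fr3,    node: treg_fr3,    class: type, fraction_group: cd4}
  - {id: cd8_t,       node: cd8_t,       class: type}
  - {id: cd8_naive,   node: cd8_naive,   class: type, fraction_group: cd8}
  - {id: cd8_cm,      node: cd8_cm,      class: type, fraction_group: cd8}
  - {id: cd8_em,      node: cd8_em,      class: type, fraction_group: cd8}
  - {id: cd8_emra,    node: cd8_emra,    class: type, fraction_group: cd8}
  - {id: nkt_cd4,     node: nkt_cd4,     class: type}
  - {id: nkt_cd8,     node: nkt_cd8,     class: type}
  - {id: b_cell,      node: b_cell,      class: type}
  - {id: nk,          node: nk,          class: type}
  - {id: cdc,         node: cdc,         class: type, fraction_group: myeloid}
  - {id: pdc,         node: pdc,         class: type, fraction_group: myeloid}
  - {id: macrophage,  node: macrophage,  class: type, fraction_group: myeloid}
  - {id: mmdsc,       node: mmdsc,       class: type, fraction_group: myeloid}
  - {id: cd14_mono,   node: cd14_mono,   class: type, fraction_group: myeloid}
  - {id: ki67_cd4t,   node: ki67_cd4t,   class: overlay, parent_population: cd4_t}
  - {id: ki67_cd8t,   node: ki67_cd8t,   class: overlay, parent_population: cd8_t}
  - {id: pd1_cd4t,    node: pd1_cd4t,    class: overlay, parent_population: cd4_t}
  - {id: pd1_cd8t,    node: pd1_cd8t,    class: overlay, parent_population: cd8_t}
  - {id: pdl1_cd8t,   node: pdl1_cd8t,   class: overlay, parent_population: cd8_t}
  - {id: pdl1_mmdsc,  node: pdl1_mmdsc,  class: overlay, parent_population: mmdsc}
  - {id: ctla4_etreg, node: ctla4_etreg, class: overlay, parent_population: treg_fr2}
denominators:
  cd45: leukocyte
  cd4: cd4_t
  cd8: cd8_t
  myeloid: [macrophage, mmdsc, cd14_mono, cdc, pdc]
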