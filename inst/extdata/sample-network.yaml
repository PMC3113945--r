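# Minimal example network in the native dialect (see the package vignette
# for the full schema). Two-step pathway, one transporter, one tRNA.
cellmapr_network: 1
organism: SAMPLE-ORG
compounds:
  - id: CPD-GLC
    name: demose
    synonyms:
      - alpha-demose
    formula: C6H12O6
  - id: CPD-G6P
    name: demose-6-phosphate
  - id: CPD-F6P
    name: fasulose-6-phosphate
  - id: CPD-ATP
    name: atp-like cofactor
  - id: CPD-EXT
    name: external demose
reactions:
  - id: RXN-HK
    name: demose kinase reaction
    substrates: {CPD-GLC: 1, CPD-ATP: 1}
    products: {CPD-G6P: 1}
    ec: [2.7.1.1]
    enzymes: [ENZ-HK]
    compartment: cytosol
    pathways: [PWY-DEMO]
  - id: RXN-ISO
    name: demose-phosphate isomerase reaction
    substrates: {CPD-G6P: 1}
    products: {CPD-F6P: 1}
    ec: [5.3.1.9]
    enzymes: [ENZ-ISO]
    compartment: cytosol
    pathways: [PWY-DEMO]
  - id: TRXN-GLC
    name: transport of demose
    substrates: {CPD-EXT: 1}
    products: {CPD-GLC: 1}
    enzymes: [TPT-GLC]
    compartment: inner_membrane
proteins:
  - id: ENZ-HK
    name: demokinase
    enzyme: true
    genes: [G-HK]
  - id: ENZ-ISO
    name: demoisomerase
    enzyme: true
    genes: [G-ISO]
  - id: TPT-GLC
    name: demose permease
    transporter: true
    genes: [G-TPT]
rnas:
  - id: TRNA-ARG
    name: tRNA-arg
    genes: [G-TRNA]
genes:
  - id: G-HK
    name: demA
    products: [ENZ-HK]
  - id: G-ISO
    name: demB
    products: [ENZ-ISO]
  - id: G-TPT
    name: argT
    products: [TPT-GLC]
  - id: G-TRNA
    name: argR
    products: [TRNA-ARG]
pathways:
  - id: PWY-DEMO
    name: demose degradation I
    reactions: [RXN-HK, RXN-ISO]
    category: catabolic
    cluster: sugar degradation
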