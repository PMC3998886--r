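# Variant scenario: the MDS clone matures fully. The dysplastic stage
# divides and feeds an MDS-derived mature peripheral-blood pool with a much
# higher apoptosis rate than normal mature cells (half-life 16 h, i.e.
# d = ln(2) / (16/24) ~ 1.0397 /d). MDS mature cells count toward the
# proliferation-signal pool like any other mature peripheral-blood cells.
preset: mds_full_maturation
variant: mds_full_maturation
feedback:
  k_p: 4.625e-15
  k_a: 1.042e-14
  niche_depth: 3
  apoptosis_visibility: 1.0
lineages:
- label: normal
  compartments:
  - {name: LT-HSC,    a_max: 0.70, p_max: 0.02, d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: ST-HSC,    a_max: 0.65, p_max: 0.05, d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: MPP,       a_max: 0.60, p_max: 0.13, d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: CPC,       a_max: 0.55, p_max: 0.35, d: 0.0, divides: true,  in_niche: false, in_pb: false}
  - {name: precursor, a_max: 0.50, p_max: 0.70, d: 0.0, divides: true,  in_niche: false, in_pb: false}
  - {name: mature,    a_max: 0.0,  p_max: 0.0,  d: 2.3, divides: false, in_niche: false, in_pb: true}
- label: mds
  compartments:
  - {name: LT-HSC,    a_max: 0.90,   p_max: 0.01,    d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: ST-HSC,    a_max: 0.7772, p_max: 0.04528, d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: MPP,       a_max: 0.65,   p_max: 0.1265,  d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: CPC,       a_max: 0.60,   p_max: 0.1626,  d: 0.0, divides: true,  in_niche: false, in_pb: false}
  - {name: precursor, a_max: 0.55,   p_max: 0.30,    d: 0.0, divides: true,  in_niche: false, in_pb: false}
  - {name: mature,    a_max: 0.0,    p_max: 0.0,     d: 1.0397207708399179, divides: false, in_niche: false, in_pb: true}
provenance:
  mds.mature.d: literature (half-life time only 16 h)
  mds.precursor: assumption (monotone interpolation along the hierarchy)
  everything_else: shared with mds_baseline
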