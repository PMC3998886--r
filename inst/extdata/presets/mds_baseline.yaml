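# Default two-lineage disease scenario: six-stage normal hematopoiesis
# competing with a five-stage MDS clone through shared feedback signals.
# Stem-cell contrasts and terminal death rates are literature values
# (provenance "literature"); intermediate-compartment rates and feedback gains
# are calibrated once so that, seeding a single MDS-LT-HSC into the healthy
# steady state, the simulated disease course reproduces the published
# timeline (bone-marrow composition at year 17, mature-cell collapse within
# the following years, apoptotic-cell peak of ~5.6%).
preset: mds_baseline
variant: baseline
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
  - {name: LT-HSC,     a_max: 0.90,   p_max: 0.01,    d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: ST-HSC,     a_max: 0.7772, p_max: 0.04528, d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: MPP,        a_max: 0.65,   p_max: 0.1265,  d: 0.0, divides: true,  in_niche: true,  in_pb: false}
  - {name: CPC,        a_max: 0.60,   p_max: 0.1626,  d: 0.0, divides: true,  in_niche: false, in_pb: false}
  - {name: dysplastic, a_max: 0.0,    p_max: 0.0,     d: 0.1, divides: false, in_niche: false, in_pb: false}
provenance:
  normal.LT-HSC.a_max: literature (maximal self-renewal up to 70%)
  normal.LT-HSC.p_max: literature (division at most once per 50 d)
  normal.ST-HSC: assumption (monotone interpolation along the hierarchy)
  normal.MPP: assumption (monotone interpolation along the hierarchy)
  normal.CPC: assumption (monotone interpolation along the hierarchy)
  normal.precursor: assumption (monotone interpolation along the hierarchy)
  normal.mature.d: reference-model (mature leukocyte clearance ~2.3/d)
  mds.LT-HSC.a_max: literature (maximal self-renewal up to 90%)
  mds.LT-HSC.p_max: literature (division at most once per 100 d)
  mds.ST-HSC: calibrated (disease-course timeline and composition)
  mds.MPP: calibrated (disease-course timeline and composition)
  mds.CPC: calibrated (disease-course timeline and composition)
  mds.dysplastic.d: literature (dysplastic precursors die within 10 days)
  feedback.k_a: calibrated (absolute niche scale for a 1-cell seed)
  feedback.k_p: calibrated (healthy proliferation signal 0.85)
  feedback.niche_depth: literature (three most primitive compartments)
  feedback.apoptosis_visibility: literature (apoptosis takes 24 h)
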