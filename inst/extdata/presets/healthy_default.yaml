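# Six-stage normal hematopoiesis alone (no malignant clone); its analytic
# steady state is the baseline for every disease scenario.
preset: healthy_default
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
provenance:
  normal.LT-HSC.a_max: literature (maximal self-renewal up to 70%)
  normal.LT-HSC.p_max: literature (division at most once per 50 d)
  normal.ST-HSC: assumption (monotone interpolation along the hierarchy)
  normal.MPP: assumption (monotone interpolation along the hierarchy)
  normal.CPC: assumption (monotone interpolation along the hierarchy)
  normal.precursor: assumption (monotone interpolation along the hierarchy)
  normal.mature.d: reference-model (mature leukocyte clearance ~2.3/d)
  feedback.k_a: calibrated (shared with mds_baseline)
  feedback.k_p: calibrated (shared with mds_baseline)
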