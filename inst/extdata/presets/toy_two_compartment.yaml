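# Hand-solvable two-compartment system (one dividing stem pool feeding a
# mature pool) used for analytic tests: the stem fixed point is
# W* = (2 a_max - 1) / k_a with niche signal 1 / (2 a_max).
preset: toy_two_compartment
variant: baseline
feedback:
  k_p: 1.0e-6
  k_a: 1.0e-6
  niche_depth: 1
  apoptosis_visibility: 1.0
lineages:
- label: normal
  compartments:
  - {name: stem,   a_max: 0.7, p_max: 0.1, d: 0.0, divides: true,  in_niche: true, in_pb: false}
  - {name: mature, a_max: 0.0, p_max: 0.0, d: 1.0, divides: false, in_niche: false, in_pb: true}
provenance:
  all: assumption (toy fixture)
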