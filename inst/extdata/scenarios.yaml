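# Scenario catalogue for the NSCLC G1/S-checkpoint model.
# Each scenario fixes the DNA_Damage input, clamps zero or more nodes
# (0 = knockout/KO, 1 = ectopic expression/E1) and records the
# phenotypes expected among the reachable attractors.
WT_no_damage:
  input: 0
  clamps: {}
  expected: [Proliferation]
WT_damage:
  input: 1
  clamps: {}
  expected: [Senescence, Apoptosis]
UFC1_KO:
  input: 1
  clamps: {UFC1: 0}
  expected: [Senescence, Apoptosis]
ANRIL_KO:
  input: 1
  clamps: {ANRIL: 0}
  expected: [Senescence, Apoptosis]
ANRIL_KO_UFC1_KO:
  input: 1
  clamps: {ANRIL: 0, UFC1: 0}
  expected: [Senescence, Apoptosis]
UFC1_E1:
  input: 1
  clamps: {UFC1: 1}
  expected: [Apoptosis]
ANRIL_E1:
  input: 1
  clamps: {ANRIL: 1}
  expected: [Apoptosis]
UFC1_E1_no_damage:
  input: 0
  clamps: {UFC1: 1}
  expected: [Proliferation]
ANRIL_E1_no_damage:
  input: 0
  clamps: {ANRIL: 1}
  expected: [Proliferation]
UFC1_KO_miR34a_KO:
  input: 1
  clamps: {UFC1: 0, miR34a: 0}
  expected: [Apoptosis]
ANRIL_KO_miR34a_KO:
  input: 1
  clamps: {ANRIL: 0, miR34a: 0}
  expected: [Apoptosis]
miR34a_KO:
  input: 1
  clamps: {miR34a: 0}
  expected: [Apoptosis]
miR34a_E1:
  input: 1
  clamps: {miR34a: 1}
  expected: [Senescence, Apoptosis]
Myc_KO:
  input: 1
  clamps: {Myc: 0}
  expected: [Senescence, Apoptosis]
Myc_E1:
  input: 1
  clamps: {Myc: 1}
  expected: [Apoptosis]
UFC1_KO_miR34a_E1:
  input: 1
  clamps: {UFC1: 0, miR34a: 1}
  expected: [Senescence, Apoptosis]
ANRIL_KO_miR34a_E1:
  input: 1
  clamps: {ANRIL: 0, miR34a: 1}
  expected: [Senescence, Apoptosis]
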