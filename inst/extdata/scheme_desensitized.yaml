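# Variant of the shipped gating scheme in which the inhibitor stabilizes
# desensitized states instead of the pre-active state: inhibitor Kd is
# 1 uM on the desensitized states and 100 uM elsewhere, with the
# inhibitor-layer resensitization rate adjusted to close every
# thermodynamic cycle. A slow unliganded desensitization pathway (R <-> D)
# makes the deep inhibitor-bound desensitized state reachable during
# pre-application, which is what lets a desensitization-stabilizing
# inhibitor suppress the subsequent peak response. Placeholder rates, see
# scheme_preactive.yaml.
states:
  - {name: R,   class: resting}
  - {name: RI,  class: resting,       inhibitor_bound: true}
  - {name: D,   class: desensitized}
  - {name: DI,  class: desensitized,  inhibitor_bound: true}
  - {name: A,   class: agonist-bound}
  - {name: AI,  class: agonist-bound, inhibitor_bound: true}
  - {name: AF,  class: pre-active}
  - {name: AFI, class: pre-active,    inhibitor_bound: true}
  - {name: AO,  class: open,          conducting: true}
  - {name: AOI, class: open,          conducting: true, inhibitor_bound: true}
  - {name: AD,  class: desensitized}
  - {name: ADI, class: desensitized,  inhibitor_bound: true}
transitions:
  - {from: R,   to: A,   rate: 2.0e4, ligand: agonist}
  - {from: A,   to: R,   rate: 20}
  - {from: RI,  to: AI,  rate: 2.0e4, ligand: agonist}
  - {from: AI,  to: RI,  rate: 20}
  - {from: A,   to: AF,  rate: 20}
  - {from: AF,  to: A,   rate: 50}
  - {from: AI,  to: AFI, rate: 20}
  - {from: AFI, to: AI,  rate: 50}
  - {from: AF,  to: AO,  rate: 500}
  - {from: AO,  to: AF,  rate: 100}
  - {from: AFI, to: AOI, rate: 500}
  - {from: AOI, to: AFI, rate: 100}
  - {from: AO,  to: AD,  rate: 0.5}
  - {from: AD,  to: AO,  rate: 0.05}
  - {from: AOI, to: ADI, rate: 0.5}
  - {from: ADI, to: AOI, rate: 0.0005}  # desensitization equilibrium x100
  - {from: R,   to: RI,  rate: 1.0e6, ligand: inhibitor}
  - {from: RI,  to: R,   rate: 100}
  - {from: A,   to: AI,  rate: 1.0e6, ligand: inhibitor}
  - {from: AI,  to: A,   rate: 100}
  - {from: AF,  to: AFI, rate: 1.0e6, ligand: inhibitor}
  - {from: AFI, to: AF,  rate: 100}
  - {from: AO,  to: AOI, rate: 1.0e6, ligand: inhibitor}
  - {from: AOI, to: AO,  rate: 100}
  - {from: AD,  to: ADI, rate: 1.0e6, ligand: inhibitor}
  - {from: ADI, to: AD,  rate: 1}
  # unliganded desensitization, strongly amplified by inhibitor binding
  - {from: R,   to: D,   rate: 0.1}
  - {from: D,   to: R,   rate: 1}
  - {from: D,   to: DI,  rate: 1.0e6, ligand: inhibitor}
  - {from: DI,  to: D,   rate: 1}
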