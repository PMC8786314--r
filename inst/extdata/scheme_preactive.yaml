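# Agonist-gated scheme with resting (R), agonist-bound (A), pre-active
# "flipped" (AF), open (AO) and desensitized (AD) states, each with an
# inhibitor-bound copy (suffix I). The inhibitor binds every state but is
# 100x tighter on the pre-active state (Kd 1 uM vs 100 uM elsewhere);
# the inhibitor-layer gating rates are adjusted so every binding/gating
# cycle satisfies microscopic reversibility. Rates are placeholders chosen
# to reproduce the qualitative inhibition phenotypes (reduced peak, faster
# and deeper decay, pre-active accumulation at steady state); they are not
# fitted to any experimental recording.
states:
  - {name: R,   class: resting}
  - {name: RI,  class: resting,       inhibitor_bound: true}
  - {name: A,   class: agonist-bound}
  - {name: AI,  class: agonist-bound, inhibitor_bound: true}
  - {name: AF,  class: pre-active}
  - {name: AFI, class: pre-active,    inhibitor_bound: true}
  - {name: AO,  class: open,          conducting: true}
  - {name: AOI, class: open,          conducting: true, inhibitor_bound: true}
  - {name: AD,  class: desensitized}
  - {name: ADI, class: desensitized,  inhibitor_bound: true}
transitions:
  # agonist binding (rate in s^-1 M^-1)
  - {from: R,   to: A,   rate: 2.0e4, ligand: agonist}
  - {from: A,   to: R,   rate: 20}
  - {from: RI,  to: AI,  rate: 2.0e4, ligand: agonist}
  - {from: AI,  to: RI,  rate: 20}
  # flipping (pre-activation)
  - {from: A,   to: AF,  rate: 20}
  - {from: AF,  to: A,   rate: 50}
  - {from: AI,  to: AFI, rate: 20}
  - {from: AFI, to: AI,  rate: 0.5}     # flip equilibrium x100 when inhibited
  # opening
  - {from: AF,  to: AO,  rate: 500}
  - {from: AO,  to: AF,  rate: 100}
  - {from: AFI, to: AOI, rate: 5}       # opening equilibrium /100
  - {from: AOI, to: AFI, rate: 100}
  # desensitization
  - {from: AO,  to: AD,  rate: 0.5}
  - {from: AD,  to: AO,  rate: 0.05}
  - {from: AOI, to: ADI, rate: 0.5}
  - {from: ADI, to: AOI, rate: 0.05}
  # inhibitor binding (rate in s^-1 M^-1); Kd 100 uM except AF (1 uM)
  - {from: R,   to: RI,  rate: 1.0e6, ligand: inhibitor}
  - {from: RI,  to: R,   rate: 100}
  - {from: A,   to: AI,  rate: 1.0e6, ligand: inhibitor}
  - {from: AI,  to: A,   rate: 100}
  - {from: AF,  to: AFI, rate: 1.0e6, ligand: inhibitor}
  - {from: AFI, to: AF,  rate: 1}
  - {from: AO,  to: AOI, rate: 1.0e6, ligand: inhibitor}
  - {from: AOI, to: AO,  rate: 100}
  - {from: AD,  to: ADI, rate: 1.0e6, ligand: inhibitor}
  - {from: ADI, to: AD,  rate: 100}
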