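# Default species configuration for the synthetic coarse-grained system:
# residue name -> species token, headgroup bead names, protein flag.
POPC: {headgroup_beads: [PO4]}
POPE: {headgroup_beads: [PO4]}
POPG: {headgroup_beads: [PO4]}
DHA:  {headgroup_beads: [COO]}
PA:   {headgroup_beads: [COO]}
GLY:  {protein: true}
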