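# Dual-state template for 1-methylimidazolium (IM1H, +1 e) and
# 1-methylimidazole (IM1, 0 e) in the polarizable Drude general force field
# nomenclature. LJ well depths and polarizabilities are stored as
# magnitudes. The acidic ring hydrogen H7 (type HDP1A) becomes the dummy
# DUMH in the neutral state; the lone pair LPN21 on the unsubstituted ring
# nitrogen N2 is switched off (charge 0) in the protonated state.
residue_pairs:
  - name_protonated: IM1H
    name_deprotonated: IM1
    donor_atoms: [H7]
    acceptor_atoms: [N2]
    dummy_atoms: [H7]
    atoms:
      - name: C1
        protonated:   {type: CD33F, lj_epsilon: 0.0486, lj_rmin_half: 2.040, charge: -0.182, polarizability: 1.181, thole: 1.1}
        deprotonated: {type: CD33G, lj_epsilon: 0.0513, lj_rmin_half: 2.040, charge: -0.161, polarizability: 1.081, thole: 1.0}
      - name: H1
        protonated:   {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.135}
        deprotonated: {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.094}
      - name: H2
        protonated:   {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.135}
        deprotonated: {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.094}
      - name: H3
        protonated:   {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.135}
        deprotonated: {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.094}
      - name: N1
        protonated:   {type: ND2R5C, lj_epsilon: 0.0791, lj_rmin_half: 1.850, charge: 0.158, polarizability: 0.803, thole: 1.0}
        deprotonated: {type: ND2R5A, lj_epsilon: 0.0578, lj_rmin_half: 1.861, charge: 0.140, polarizability: 1.063, thole: 1.3}
      - name: C2
        protonated:   {type: CD2R5D, lj_epsilon: 0.0329, lj_rmin_half: 1.800, charge: -0.107, polarizability: 1.083, thole: 1.1}
        deprotonated: {type: CD2R5A, lj_epsilon: 0.0523, lj_rmin_half: 2.070, charge: -0.369, polarizability: 1.378, thole: 1.3}
      - name: H4
        protonated:   {type: HDR5D, lj_epsilon: 0.0350, lj_rmin_half: 0.700, charge: 0.195}
        deprotonated: {type: HDR5A, lj_epsilon: 0.0550, lj_rmin_half: 1.250, charge: 0.150}
      - name: C3
        protonated:   {type: CD2R5D, lj_epsilon: 0.0329, lj_rmin_half: 1.800, charge: -0.047, polarizability: 1.083, thole: 1.1}
        deprotonated: {type: CD2R5A, lj_epsilon: 0.0523, lj_rmin_half: 2.070, charge: 0.188, polarizability: 1.378, thole: 1.3}
      - name: H5
        protonated:   {type: HDR5D, lj_epsilon: 0.0350, lj_rmin_half: 0.700, charge: 0.192}
        deprotonated: {type: HDR5A, lj_epsilon: 0.0550, lj_rmin_half: 1.250, charge: 0.053}
      - name: C4
        protonated:   {type: CD2R5E, lj_epsilon: 0.0597, lj_rmin_half: 1.850, charge: -0.023, polarizability: 1.253, thole: 1.2}
        deprotonated: {type: CD2R5B, lj_epsilon: 0.0680, lj_rmin_half: 1.980, charge: 0.118, polarizability: 0.868, thole: 1.3}
      - name: H6
        protonated:   {type: HDR5E, lj_epsilon: 0.1000, lj_rmin_half: 0.550, charge: 0.203}
        deprotonated: {type: HDR5B, lj_epsilon: 0.0870, lj_rmin_half: 1.103, charge: 0.073}
      - name: N2
        protonated:   {type: ND2R5C, lj_epsilon: 0.0791, lj_rmin_half: 1.850, charge: -0.157, polarizability: 0.803, thole: 1.0}
        deprotonated: {type: ND2R5B, lj_epsilon: 0.0511, lj_rmin_half: 1.956, charge: 0.000, polarizability: 0.840, thole: 1.0}
      - name: H7
        protonated:   {type: HDP1A, lj_epsilon: 0.0100, lj_rmin_half: 0.400, charge: 0.363}
        deprotonated: {type: DUMH, lj_epsilon: 0.0000, lj_rmin_half: 0.010, charge: 0.000}
      - name: LPN21
        protonated:   {type: LPD, lj_epsilon: 0.0000, lj_rmin_half: 0.010, charge: 0.000}
        deprotonated: {type: LPD, lj_epsilon: 0.0000, lj_rmin_half: 0.010, charge: -0.474}
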