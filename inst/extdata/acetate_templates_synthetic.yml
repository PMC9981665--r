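# SYNTHETIC stand-in for the acetic acid (HOAC, 0 e) / acetate (OAC-, -1 e)
# dual template. The published parameter tables for this pair are not
# available to the package, so the values below are constructed: charges
# are chemically plausible and sum exactly to 0 / -1 e, LJ parameters are
# generic CGenFF-scale values. The topology (acidic hydrogen H7 turning
# into the dummy DUMH, both carboxylate oxygens acting as acceptor sites)
# follows the published scheme. Do not use for production force fields.
residue_pairs:
  - name_protonated: HOAC
    name_deprotonated: OAC
    donor_atoms: [H7]
    acceptor_atoms: [O1, O2]
    dummy_atoms: [H7]
    atoms:
      - name: C1
        protonated:   {type: CD33A, lj_epsilon: 0.0780, lj_rmin_half: 2.040, charge: -0.270, polarizability: 1.100, thole: 1.1}
        deprotonated: {type: CD33B, lj_epsilon: 0.0780, lj_rmin_half: 2.040, charge: -0.370, polarizability: 1.150, thole: 1.1}
      - name: H1
        protonated:   {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.090}
        deprotonated: {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.090}
      - name: H2
        protonated:   {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.090}
        deprotonated: {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.090}
      - name: H3
        protonated:   {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.090}
        deprotonated: {type: HDA3A, lj_epsilon: 0.0240, lj_rmin_half: 1.340, charge: 0.090}
      - name: C2
        protonated:   {type: CD2O2A, lj_epsilon: 0.0700, lj_rmin_half: 2.000, charge: 0.750, polarizability: 1.200, thole: 1.2}
        deprotonated: {type: CD2O3A, lj_epsilon: 0.0700, lj_rmin_half: 2.000, charge: 0.620, polarizability: 1.250, thole: 1.2}
      - name: O1
        protonated:   {type: OD2C2A, lj_epsilon: 0.1200, lj_rmin_half: 1.700, charge: -0.550, polarizability: 0.900, thole: 1.1}
        deprotonated: {type: OD2C3A, lj_epsilon: 0.1200, lj_rmin_half: 1.700, charge: -0.760, polarizability: 0.950, thole: 1.1}
      - name: O2
        protonated:   {type: OD31B, lj_epsilon: 0.1200, lj_rmin_half: 1.720, charge: -0.610, polarizability: 0.900, thole: 1.1}
        deprotonated: {type: OD2C3A, lj_epsilon: 0.1200, lj_rmin_half: 1.700, charge: -0.760, polarizability: 0.950, thole: 1.1}
      - name: H7
        protonated:   {type: HDP1A, lj_epsilon: 0.0100, lj_rmin_half: 0.400, charge: 0.410}
        deprotonated: {type: DUMH, lj_epsilon: 0.0000, lj_rmin_half: 0.010, charge: 0.000}
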