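# The four proton-transfer reactions of the imidazolium acetate system.
# Probabilities are given on the percent scale and converted to fractions
# on load. The monitor species of the cubic feedback rule defaults to the
# first reactant. All reactions share the 1.55 Angstrom donor-acceptor
# distance criterion and feedback constant c = 300.
reactions:
  - reactants: [IM1H, OAC]
    products: [IM1, HOAC]
    r_max: 1.55
    p_ref_percent: 99.4
    c: 300
  - reactants: [IM1, HOAC]
    products: [IM1H, OAC]
    r_max: 1.55
    p_ref_percent: 9.8
    c: 300
  - reactants: [IM1H, IM1]
    products: [IM1, IM1H]
    r_max: 1.55
    p_ref_percent: 20.1
    c: 300
  - reactants: [HOAC, OAC]
    products: [OAC, HOAC]
    r_max: 1.55
    p_ref_percent: 68.4
    c: 300
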