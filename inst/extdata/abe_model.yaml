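note: 'Default ABE network with butyryl-phosphate: 17 species, 21 reactions, 50 kinetic
  parameters. Reconstructed topology; R16 (AADC) produces acetone. Butyrate branch:
  BCoA -R18(PTB)-> BuP -R20(BK)-> But and But -R17(BK)-> BuP -R21(PTB)-> BCoA.'
species:
- id: Glc
  name: glucose
  role: external-substrate
- id: F6P
  name: fructose-6-phosphate
  role: intermediate
- id: G3P
  name: glyceraldehyde-3-phosphate
  role: intermediate
- id: Pyr
  name: pyruvate
  role: intermediate
- id: Lac
  name: lactate
  role: intermediate
- id: ACoA
  name: acetyl-CoA
  role: intermediate
- id: AACoA
  name: acetoacetyl-CoA
  role: intermediate
- id: AcAc
  name: acetoacetate
  role: intermediate
- id: Ace
  name: acetate
  role: intermediate
- id: EtOH
  name: ethanol
  role: end-product
- id: Actn
  name: acetone
  role: end-product
- id: BCoA
  name: butyryl-CoA
  role: intermediate
- id: But
  name: butyrate
  role: intermediate
- id: BuOH
  name: butanol
  role: end-product
- id: CO2
  name: carbon dioxide
  role: end-product
- id: X
  name: biomass
  role: end-product
- id: BuP
  name: butyryl-phosphate
  role: intermediate
reactions:
- id: R1
  enzyme: PTS
  stoich:
    Glc: -1.0
    F6P: 1.0
  kind: substrate_inhibition
  substrates:
  - Glc
  params:
    Vmax:
    - Vmax1
    Km:
    - Km1
    Ki:
    - Ki1
  regulated: no
- id: R2
  enzyme: GLY1
  stoich:
    F6P: -1.0
    G3P: 2.0
  kind: mass_action
  substrates:
  - F6P
  params:
    k:
    - k2
  regulated: no
- id: R3
  enzyme: GLY2
  stoich:
    G3P: -1.0
    Pyr: 1.0
  kind: mass_action
  substrates:
  - G3P
  params:
    k:
    - k3
  regulated: no
- id: R4
  enzyme: LDH
  stoich:
    Pyr: -1.0
    Lac: 1.0
  kind: michaelis_menten
  substrates:
  - Pyr
  params:
    Vmax:
    - Vmax4
    Km:
    - Km4
  regulated: no
- id: R5
  enzyme: PFOR
  stoich:
    Pyr: -1.0
    ACoA: 1.0
    CO2: 1.0
  kind: michaelis_menten
  substrates:
  - Pyr
  params:
    Vmax:
    - Vmax5
    Km:
    - Km5
  regulated: no
- id: R6
  enzyme: BIO
  stoich:
    ACoA: -1.0
    X: 1.0
  kind: michaelis_menten
  substrates:
  - ACoA
  params:
    Vmax:
    - Vmax6
    Km:
    - Km6
  regulated: no
- id: R7
  enzyme: AK
  stoich:
    Ace: -1.0
    ACoA: 1.0
  kind: michaelis_menten
  substrates:
  - Ace
  params:
    Vmax:
    - Vmax7
    Km:
    - Km7
  regulated: yes
- id: R8
  enzyme: CoAT
  stoich:
    Ace: -1.0
    AACoA: -1.0
    AcAc: 1.0
    ACoA: 1.0
  kind: product_inhibition
  substrates:
  - Ace
  - AACoA
  params:
    Vmax:
    - Vmax8
    Km:
    - Km8a
    - Km8b
    Ki:
    - Ki8
  regulated: yes
  effector: AcAc
- id: R9
  enzyme: PTA
  stoich:
    ACoA: -1.0
    Ace: 1.0
  kind: michaelis_menten
  substrates:
  - ACoA
  params:
    Vmax:
    - Vmax9
    Km:
    - Km9
  regulated: yes
- id: R10
  enzyme: THL
  stoich:
    ACoA: -2.0
    AACoA: 1.0
  kind: product_inhibition
  substrates:
  - ACoA
  params:
    Vmax:
    - Vmax10
    Km:
    - Km10
    Ki:
    - Ki10
  regulated: no
  effector: BuOH
- id: R11
  enzyme: AAD
  stoich:
    ACoA: -1.0
    EtOH: 1.0
  kind: activation
  substrates:
  - ACoA
  params:
    Vmax:
    - Vmax11
    Km:
    - Km11
    Ka:
    - Ka11
  regulated: yes
  effector: But
- id: R12
  enzyme: THL
  stoich:
    AACoA: -1.0
    ACoA: 2.0
  kind: michaelis_menten
  substrates:
  - AACoA
  params:
    Vmax:
    - Vmax12
    Km:
    - Km12
  regulated: no
- id: R13
  enzyme: LDH
  stoich:
    Lac: -1.0
    Pyr: 1.0
  kind: michaelis_menten
  substrates:
  - Lac
  params:
    Vmax:
    - Vmax13
    Km:
    - Km13
  regulated: no
- id: R14
  enzyme: B-C-B
  stoich:
    AACoA: -1.0
    BCoA: 1.0
  kind: product_inhibition
  substrates:
  - AACoA
  params:
    Vmax:
    - Vmax14
    Km:
    - Km14
    Ki:
    - Ki14
  regulated: yes
  effector: BuOH
- id: R15
  enzyme: CoAT
  stoich:
    But: -1.0
    AACoA: -1.0
    AcAc: 1.0
    BCoA: 1.0
  kind: product_inhibition
  substrates:
  - But
  - AACoA
  params:
    Vmax:
    - Vmax15
    Km:
    - Km15a
    - Km15b
    Ki:
    - Ki15
  regulated: yes
  effector: AcAc
- id: R16
  enzyme: AADC
  stoich:
    AcAc: -1.0
    Actn: 1.0
    CO2: 1.0
  kind: michaelis_menten
  substrates:
  - AcAc
  params:
    Vmax:
    - Vmax16
    Km:
    - Km16
  regulated: yes
- id: R17
  enzyme: BK
  stoich:
    But: -1.0
    BuP: 1.0
  kind: substrate_inhibition
  substrates:
  - But
  params:
    Vmax:
    - Vmax17
    Km:
    - Km17
    Ki:
    - Ki17
  regulated: yes
- id: R18
  enzyme: PTB
  stoich:
    BCoA: -1.0
    BuP: 1.0
  kind: michaelis_menten
  substrates:
  - BCoA
  params:
    Vmax:
    - Vmax18
    Km:
    - Km18
  regulated: yes
- id: R19
  enzyme: BDH
  stoich:
    BCoA: -1.0
    BuOH: 1.0
  kind: activation
  substrates:
  - BCoA
  params:
    Vmax:
    - Vmax19
    Km:
    - Km19
    Ka:
    - Ka19
  regulated: yes
  effector: But
- id: R20
  enzyme: BK
  stoich:
    BuP: -1.0
    But: 1.0
  kind: michaelis_menten
  substrates:
  - BuP
  params:
    Vmax:
    - Vmax20
    Km:
    - Km20
  regulated: yes
- id: R21
  enzyme: PTB
  stoich:
    BuP: -1.0
    BCoA: 1.0
  kind: michaelis_menten
  substrates:
  - BuP
  params:
    Vmax:
    - Vmax21
    Km:
    - Km21
  regulated: yes
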