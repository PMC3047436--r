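# C16-branch sphingolipid reaction network (RAW264.7 macrophage model).
# One record per reaction. `factors` are the mass-action rate factors
# (dynamic metabolites, input lipids, or gene/protein fold-changes);
# `consumes`/`produces` list only dynamic metabolites (stoichiometry).
# Degradation reactions produce nothing tracked (leaf-branch losses to
# DHGalCer/GalCer are absorbed into the default degradations).
species:
  dynamic: [C16DHCer, DHSph1P, C16DHGlcCer, C16DHSM, C16DHCerP,
            C16Cer, C16CerP, C16SM, C16GlcCer]
  input_lipids: [DHSph, CoA16, C16DG, C16GPCho]
  genes: [CerS6, Sphk1, Sphk2, Ugcg, Sms1, Sms2, Smpd1, Cerk, Degs1]
reactions:
  - id: 1
    forward: {param: kf1, factors: [DHSph, CoA16, CerS6]}
    consumes: []
    produces: [C16DHCer]
  - id: 2
    forward: {param: kf2, factors: [DHSph, CoA16]}
    consumes: []
    produces: [C16DHCer]
  - id: 3
    forward: {param: kf3, factors: [C16DHCer]}
    consumes: [C16DHCer]
    produces: []
  - id: 4
    forward: {param: kf4, factors: [DHSph, Sphk1]}
    consumes: []
    produces: [DHSph1P]
  - id: 5
    forward: {param: kf5, factors: [DHSph, Sphk2]}
    consumes: []
    produces: [DHSph1P]
  - id: 6
    forward: {param: kf6, factors: [DHSph1P]}
    consumes: [DHSph1P]
    produces: []
  - id: 7
    forward: {param: kf7, factors: [C16DHCer, Ugcg]}
    consumes: [C16DHCer]
    produces: [C16DHGlcCer]
  - id: 8
    forward: {param: kf8, factors: [C16DHGlcCer]}
    consumes: [C16DHGlcCer]
    produces: []
  - id: 9
    forward: {param: kf9, factors: [C16DHCer, Sms1, C16GPCho]}
    backward: {param: kb9, factors: [C16DHSM, Sms1, C16DG]}
    consumes: [C16DHCer]
    produces: [C16DHSM]
  - id: 10
    forward: {param: kf10, factors: [C16DHCer, Sms2, C16GPCho]}
    backward: {param: kb10, factors: [C16DHSM, Sms2, C16DG]}
    consumes: [C16DHCer]
    produces: [C16DHSM]
  - id: 11
    forward: {param: kf11, factors: [C16DHSM, Smpd1]}
    consumes: [C16DHSM]
    produces: [C16DHCer]
  - id: 12
    forward: {param: kf12, factors: [C16DHSM]}
    consumes: [C16DHSM]
    produces: []
  - id: 13
    forward: {param: kf13, factors: [C16DHCer, Cerk]}
    consumes: [C16DHCer]
    produces: [C16DHCerP]
  - id: 14
    forward: {param: kf14, factors: [C16DHCerP]}
    consumes: [C16DHCerP]
    produces: []
  - id: 15
    forward: {param: kf15, factors: [C16DHCer, Degs1]}
    consumes: [C16DHCer]
    produces: [C16Cer]
  - id: 16
    forward: {param: kf16, factors: [C16DHCer]}
    consumes: [C16DHCer]
    produces: [C16Cer]
  - id: 17
    forward: {param: kf17, factors: [C16Cer, Cerk]}
    consumes: [C16Cer]
    produces: [C16CerP]
  - id: 18
    forward: {param: kf18, factors: [C16CerP]}
    consumes: [C16CerP]
    produces: []
  - id: 19
    forward: {param: kf19, factors: [C16Cer, Sms1, C16GPCho]}
    backward: {param: kb19, factors: [C16SM, Sms1, C16DG]}
    consumes: [C16Cer]
    produces: [C16SM]
  - id: 20
    forward: {param: kf20, factors: [C16Cer, Sms2, C16GPCho]}
    backward: {param: kb20, factors: [C16SM, Sms2, C16DG]}
    consumes: [C16Cer]
    produces: [C16SM]
  - id: 21
    forward: {param: kf21, factors: [C16SM, Smpd1]}
    consumes: [C16SM]
    produces: [C16Cer]
  - id: 22
    forward: {param: kf22, factors: [C16SM]}
    consumes: [C16SM]
    produces: []
  - id: 23
    forward: {param: kf23, factors: [C16Cer]}
    consumes: [C16Cer]
    produces: []
  - id: 24
    forward: {param: kf24, factors: [C16Cer, Ugcg]}
    consumes: [C16Cer]
    produces: [C16GlcCer]
  - id: 25
    forward: {param: kf25, factors: [C16GlcCer]}
    consumes: [C16GlcCer]
    produces: []
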