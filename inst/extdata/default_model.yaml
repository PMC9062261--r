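# cardiomyosim model definition
compartments:
  vessel: 0.06842
  extracellular: 0.24063
  cytosol:  1
  ims: 0.0715
  matrix: 0.6435
species:
  - {name: AMP_c, compartment: cytosol, unit: mM, initial: 1e-05, kind: ode}
  - {name: ADP_c, compartment: cytosol, unit: mM, initial: 1e-05, kind: ode}
  - {name: ATP_c, compartment: cytosol, unit: mM, initial:  7, kind: ode}
  - {name: NAD_c, compartment: cytosol, unit: mM, initial: 2.2565, kind: constant}
  - {name: NADH_c, compartment: cytosol, unit: mM, initial: 0.7135, kind: constant}
  - {name: GLC_c, compartment: cytosol, unit: mM, initial: 1.91, kind: constant}
  - {name: BPG13_c, compartment: cytosol, unit: mM, initial: 0.000869, kind: ode}
  - {name: PG2_c, compartment: cytosol, unit: mM, initial: 0.009, kind: ode}
  - {name: PG3_c, compartment: cytosol, unit: mM, initial: 0.071, kind: ode}
  - {name: Cr_c, compartment: cytosol, unit: mM, initial:  0, kind: ode}
  - {name: CrP_c, compartment: cytosol, unit: mM, initial:  25, kind: ode}
  - {name: DHAP_c, compartment: cytosol, unit: mM, initial: 0.036, kind: ode}
  - {name: F16BP_c, compartment: cytosol, unit: mM, initial: 0.000678, kind: ode}
  - {name: F6P_c, compartment: cytosol, unit: mM, initial: 0.041, kind: ode}
  - {name: G16BP_c, compartment: cytosol, unit: mM, initial: 0.007, kind: constant}
  - {name: G1P_c, compartment: cytosol, unit: mM, initial: 0.02, kind: ode}
  - {name: G6P_c, compartment: cytosol, unit: mM, initial: 0.169, kind: ode}
  - {name: GAP_c, compartment: cytosol, unit: mM, initial: 0.00162, kind: ode}
  - {name: GLY_c, compartment: cytosol, unit: mM, initial: 21.4, kind: ode}
  - {name: LAC_c, compartment: cytosol, unit: mM, initial: 0.247, kind: ode}
  - {name: LACH_c, compartment: cytosol, unit: mM, initial: 155.84, kind: ode}
  - {name: Mb_c, compartment: cytosol, unit: mM, initial: 0.00543, kind: ode}
  - {name: MbO2_c, compartment: cytosol, unit: mM, initial: 0.18457, kind: ode}
  - {name: O2_c, compartment: cytosol, unit: mM, initial: 0.11017, kind: ode}
  - {name: PEP_c, compartment: cytosol, unit: mM, initial: 0.013, kind: ode}
  - {name: Pi_c, compartment: cytosol, unit: mM, initial:  7, kind: ode}
  - {name: PYR_c, compartment: cytosol, unit: mM, initial: 0.055, kind: ode}
  - {name: UDPG_c, compartment: cytosol, unit: mM, initial: 0.099, kind: ode}
  - {name: H_c, compartment: cytosol, unit: mM, initial: 0.000794, kind: constant}
  - {name: K_c, compartment: cytosol, unit: mM, initial: 1.5e+02, kind: constant}
  - {name: Mg_c, compartment: cytosol, unit: mM, initial:  5, kind: assignment}
  - {name: mADP_c, compartment: cytosol, unit: mM, initial: 9.35e-06, kind: assignment}
  - {name: pH_c, compartment: cytosol, unit: unitless, initial: 7.1, kind: constant}
  - {name: ADP_i, compartment: ims, unit: mM, initial: 1e+01, kind: assignment}
  - {name: fADP_i, compartment: ims, unit: mM, initial: 1e+01, kind: assignment}
  - {name: mADP_i, compartment: ims, unit: mM, initial:  0, kind: ode}
  - {name: ATP_i, compartment: ims, unit: mM, initial:  7, kind: assignment}
  - {name: fATP_i, compartment: ims, unit: mM, initial:  7, kind: assignment}
  - {name: mATP_i, compartment: ims, unit: mM, initial:  0, kind: ode}
  - {name: H_i, compartment: ims, unit: mM, initial: 7.94e-05, kind: constant}
  - {name: K_i, compartment: ims, unit: mM, initial: 1.5e+02, kind: constant}
  - {name: Pi_i, compartment: ims, unit: mM, initial:  1, kind: ode}
  - {name: Cox_i, compartment: ims, unit: mM, initial: 1.7, kind: ode}
  - {name: Cred_i, compartment: ims, unit: mM, initial:  1, kind: ode}
  - {name: dPsi, compartment: ims, unit: mV, initial: 1.7e+02, kind: ode}
  - {name: ADP_x, compartment: matrix, unit: mM, initial: 1e+01, kind: assignment}
  - {name: fADP_x, compartment: matrix, unit: mM, initial: 1e+01, kind: ode}
  - {name: mADP_x, compartment: matrix, unit: mM, initial:  0, kind: ode}
  - {name: ATP_x, compartment: matrix, unit: mM, initial:  7, kind: assignment}
  - {name: fATP_x, compartment: matrix, unit: mM, initial:  7, kind: ode}
  - {name: mATP_x, compartment: matrix, unit: mM, initial:  0, kind: ode}
  - {name: H_x, compartment: matrix, unit: mM, initial: 6.31e-05, kind: ode}
  - {name: K_x, compartment: matrix, unit: mM, initial: 1.4e+02, kind: ode}
  - {name: Mg_x, compartment: matrix, unit: mM, initial:  5, kind: ode}
  - {name: NAD_x, compartment: matrix, unit: mM, initial: 1.47, kind: ode}
  - {name: NADH_x, compartment: matrix, unit: mM, initial: 1.5, kind: ode}
  - {name: Pi_x, compartment: matrix, unit: mM, initial:  1, kind: ode}
  - {name: Q_x, compartment: matrix, unit: mM, initial: 0.55, kind: ode}
  - {name: QH2_x, compartment: matrix, unit: mM, initial: 0.8, kind: ode}
  - {name: O2_e, compartment: extracellular, unit: mM, initial: 0.1289, kind: ode}
  - {name: O2_v, compartment: vessel, unit: mM, initial: 0.1326, kind: constant}
  - {name: LAC_e, compartment: extracellular, unit: mM, initial: 0.33, kind: constant}
parameters:
  phys:
    F: 0.096484
    RT: 2.57734
    CIM: 0.00675
    rbuff: 1e+01
    aDH: 0.6435
    MgtotC:  5
    MgI:  5
    KaPi: 0.00017782794100389227
    o2PerC4: 0.5
    aF1: 1.5540015540015542
    glcCoupling:  1
    Vc:  1
    Vi: 0.0715
    Vx: 0.6435
    Ve: 0.24063
    Vv: 0.06842
  CK:
    X: 1e+04
    K: 1.66e+06
  AK:
    X: 1e+04
    K:  1
  ATPase:
    X: 0.39
    R: 0.0658
  HK:
    Vf: 0.55
    Kmf: 0.072
    KmATP: 0.236
    Vr: 0.000106
    Kmr: 0.042
  PGI:
    Vf: 10.067
    Kmf: 0.425
    Vr: 9.6
    Kmr: 0.175
  PFK:
    Vf: 1.328
    Kmf: 0.224
    KmATP: 0.127
  FBPA:
    Vf: 0.992
    Kmf: 0.038
  TPI:
    Vf: 5.933
    Kmf: 1.53
  GAPDH:
    Vf: 5.35
    Kmf: 0.042
    KmNAD: 0.058
  PGK:
    Vf:  251
    Kmf: 0.021
    KmADP: 0.565
    Vr: 15.98
    Kmr: 0.51
    KmATP: 0.008
  PGM:
    Vf: 11.233
    Kmf: 0.145
    Vr:  48
    Kmr: 0.139
  Enolase:
    Vf: 1.85
    Kmf: 0.045
    Vr:  2
    Kmr: 0.089
  PK:
    Vf: 9.433
    Kmf: 0.11
    KmADP: 0.00268
    Vr: 0.00105
    Kmr: 1e+01
  G6PDH:
    Vf: 0.095
    vss: 0.125
  G3PDH:
    Vf: 0.095
    Kia: 0.095
    KmDHAP: 0.095
    KmNADH: 0.095
  G16BPS:
    Vf: 1e+01
    Kmf: 0.021
    KmG1P: 0.008
    Vr:  6
    Kmr: 0.51
    KmG16BP: 0.565
  PGluM:
    Vf: 1.933
    Kmf: 0.045
    Vr: 1.12
    Kmr: 0.67
  UDPGP:
    X: 1e+04
    kf: 4.36
    kr: 0.881
    KmAMP: 0.016
  GS:
    VfD: 0.147
    KmD: 1.42
    VfI: 0.147
    KmI: 0.08
    KmAMP: 0.016
  GP:
    Vf: 0.782
    Kmf: 0.1
    Vr: 55.83
    Kmr:  5
    KmAMP: 0.016
  LDH:
    Vf: 23.93
    Kmf: 0.125
    KmNADH: 0.001
  LHX:
    Vf: 0.048
    Kmf: 2.2
    Vr: 0.182
    Kmr: 6.92
  LA:
    X: 1e+04
    Km: 1.259e-06
  MB:
    ka: 1.54e+04
    kd: 6e+01
  MgBc:
    KMgADP: 0.347
  MgB:
    X: 1e+03
    KMgADP: 0.347
    KMgATP: 0.024
  Pi1:
    X: 3.394e+05
    kPiH: 0.4508
  Pi2:
    p:  327
    gamma: 5.99
  ANT:
    X: 4.752
    KmADP: 0.0035
  DH:
    X: 0.092
    r: 4.581
    kPi1: 0.134
    kPi2: 0.677
  C1:
    X: 0.369
    dG0: -69.37
  C3:
    X: 0.092
    dG0: -32.53
    kPi1: 0.192
    kPi2: 25.31
  C4:
    X: 2.267e-05
    kO2: 0.003
    dG0: -122.94
  F1:
    X: 2.267e-05
    dG0: 36.03
  Hle:
    X: 0.25
  KH:
    X:  29802
  O2VE:
    pA: 5e+01
    gamma: 0.284
  O2EC:
    pA: 1e+01
    gamma: 0.241
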