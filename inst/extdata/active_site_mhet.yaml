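# Default active-site model for MHET hydrolysis by a serine hydrolase.
#
# Roles: Ser-His-Asp(Glu) catalytic triad, two backbone-NH oxyanion-hole
# donors (any amino acid except proline) and a Ser/Thr hydroxyl binding the
# terminal carboxylate of the substrate. Constraint windows encode canonical
# serine-hydrolase geometry (hydrogen-bond distances within 2-4 A, near-
# tetrahedral attack geometry at the sp3 ester carbon); every number here is
# overridable by supplying a different config file.
#
# Distances in angstrom, angles in degrees. Penalty per constraint:
# weight * (distance of the measured value outside [lo, hi])^2.

roles:
  - role_id: nucleophile_ser
    allowed_aa: [S]
    anchor_atoms: {S: {OG: [OG], CB: [CB]}}
  - role_id: base_his
    allowed_aa: [H]
    anchor_atoms: {H: {NE2: [NE2], ND1: [ND1]}}
  - role_id: acid_asp_glu
    allowed_aa: [D, E]
    anchor_atoms: {D: {OD: [OD1, OD2]}, E: {OD: [OE1, OE2]}}
  - role_id: oxyanion_nh_1
    allowed_aa: [A, C, D, E, F, G, H, I, K, L, M, N, Q, R, S, T, V, W, Y]
    anchor_atoms: {"*": {N: [N]}}
  - role_id: oxyanion_nh_2
    allowed_aa: [A, C, D, E, F, G, H, I, K, L, M, N, Q, R, S, T, V, W, Y]
    anchor_atoms: {"*": {N: [N]}}
  - role_id: carboxylate_binder_ser
    allowed_aa: [S, T]
    anchor_atoms: {S: {OG: [OG]}, T: {OG: [OG1]}}

constraints:
  - id: attack_distance
    kind: distance
    atoms: [[nucleophile_ser, OG], [TS, C1]]
    target: 2.3
    lo: 2.0
    hi: 3.0
    weight: 1.0
  - id: attack_angle
    kind: angle
    atoms: [[TS, OXY], [TS, C1], [nucleophile_ser, OG]]
    target: 109.5
    lo: 90.0
    hi: 125.0
    weight: 0.01
  - id: his_ser_hbond
    kind: distance
    atoms: [[base_his, NE2], [nucleophile_ser, OG]]
    target: 3.0
    lo: 2.5
    hi: 3.5
    weight: 1.0
  - id: his_ser_attack_angle
    kind: angle
    atoms: [[base_his, NE2], [nucleophile_ser, OG], [TS, C1]]
    target: 110.0
    lo: 80.0
    hi: 140.0
    weight: 0.005
  - id: asp_his_hbond
    kind: distance
    atoms: [[acid_asp_glu, OD], [base_his, ND1]]
    target: 2.8
    lo: 2.4
    hi: 3.5
    weight: 1.0
  - id: oxyanion_hbond_1
    kind: distance
    atoms: [[oxyanion_nh_1, N], [TS, OXY]]
    target: 2.9
    lo: 2.0
    hi: 4.0
    weight: 1.0
  - id: oxyanion_hbond_2
    kind: distance
    atoms: [[oxyanion_nh_2, N], [TS, OXY]]
    target: 2.9
    lo: 2.0
    hi: 4.0
    weight: 1.0
  - id: oxyanion_approach_angle
    kind: angle
    atoms: [[oxyanion_nh_1, N], [TS, OXY], [TS, C1]]
    target: 120.0
    lo: 90.0
    hi: 150.0
    weight: 0.005
  - id: carboxylate_hbond
    kind: distance
    atoms: [[carboxylate_binder_ser, OG], [TS, OC]]
    target: 2.8
    lo: 2.0
    hi: 4.0
    weight: 1.0

# TS pseudo-molecule: MHET first tetrahedral intermediate (TI1). C1 is the
# attacked ester carbon (sp3); OXY the oxyanion; ONU the nucleophile-side
# oxygen of the forming bond; OE the leaving ethylene-glycol ester oxygen;
# CR1-CR6 the aromatic ring; C7/O3/O4 the terminal carboxylate; C8/C9/O5 the
# ethylene glycol arm. "charge" holds partial-charge-like weights. Atom
# aliases let constraints refer to either carboxylate oxygen via "OC".
ts:
  tetrahedral_center: C1
  atom_aliases: {OC: [O3, O4]}
  atoms:
    - {name: C1 , element: C, charge:  0.60, xyz: [  0.000,   0.000,   0.000]}
    - {name: OXY, element: O, charge: -0.80, xyz: [  0.000,   0.000,   1.300]}
    - {name: ONU, element: O, charge: -0.40, xyz: [  1.602,   0.000,  -0.567]}
    - {name: OE , element: O, charge: -0.40, xyz: [ -0.674,  -1.167,  -0.477]}
    - {name: CR1, element: C, charge: -0.10, xyz: [ -0.716,   1.241,  -0.507]}
    - {name: CR2, element: C, charge: -0.10, xyz: [ -0.240,   2.508,  -0.171]}
    - {name: CR6, element: C, charge: -0.10, xyz: [ -1.850,   1.113,  -1.310]}
    - {name: CR3, element: C, charge: -0.10, xyz: [ -0.897,   3.647,  -0.636]}
    - {name: CR5, element: C, charge: -0.10, xyz: [ -2.508,   2.251,  -1.775]}
    - {name: CR4, element: C, charge: -0.10, xyz: [ -2.031,   3.518,  -1.439]}
    - {name: C7 , element: C, charge:  0.70, xyz: [ -2.734,   4.735,  -1.936]}
    - {name: O3 , element: O, charge: -0.70, xyz: [ -2.275,   5.851,  -1.612]}
    - {name: O4 , element: O, charge: -0.70, xyz: [ -3.746,   4.576,  -2.652]}
    - {name: C8 , element: C, charge:  0.05, xyz: [ -0.730,  -1.265,  -1.903]}
    - {name: C9 , element: C, charge:  0.05, xyz: [ -1.462,  -2.533,  -2.309]}
    - {name: O5 , element: O, charge: -0.50, xyz: [ -1.519,  -2.630,  -3.735]}
  bonds:
    - [C1, OXY]
    - [C1, ONU]
    - [C1, OE]
    - [C1, CR1]
    - [CR1, CR2]
    - [CR2, CR3]
    - [CR3, CR4]
    - [CR4, CR5]
    - [CR5, CR6]
    - [CR6, CR1]
    - [CR4, C7]
    - [C7, O3]
    - [C7, O4]
    - [OE, C8]
    - [C8, C9]
    - [C9, O5]
  rotatable_torsions:
    - [OXY, C1, CR1, CR2]
    - [CR3, CR4, C7, O3]
    - [C1, OE, C8, C9]
    - [OE, C8, C9, O5]
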