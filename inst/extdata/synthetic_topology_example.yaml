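chains: A
membrane_normal: 1.0
offsets:
- 3
- 4
helices:
- tm: TM1a
  chain: A
  first: 1
  last: 10
- tm: TM1b
  chain: A
  first: 11
  last: 20
- tm: TM2
  chain: A
  first: 21
  last: 40
- tm: TM3
  chain: A
  first: 41
  last: 60
- tm: TM4
  chain: A
  first: 61
  last: 80
- tm: TM5
  chain: A
  first: 81
  last: 100
- tm: TM6a
  chain: A
  first: 101
  last: 110
- tm: TM6b
  chain: A
  first: 111
  last: 120
- tm: TM7
  chain: A
  first: 121
  last: 140
- tm: TM8
  chain: A
  first: 141
  last: 160
- tm: TM9
  chain: A
  first: 161
  last: 180
- tm: TM10
  chain: A
  first: 181
  last: 200
- tm: TM11
  chain: A
  first: 201
  last: 220
- tm: TM12
  chain: A
  first: 221
  last: 240
residue_sets:
  pathway:
    mode: whole_residue
    residues:
    - chain: A
      resno: 2.0
    - chain: A
      resno: 3.0
    - chain: A
      resno: 4.0
    - chain: A
      resno: 5.0
    - chain: A
      resno: 82.0
    - chain: A
      resno: 83.0
    - chain: A
      resno: 84.0
    - chain: A
      resno: 117.0
    - chain: A
      resno: 118.0
    - chain: A
      resno: 119.0
    - chain: A
      resno: 157.0
    - chain: A
      resno: 158.0
    - chain: A
      resno: 159.0
  lid:
    mode: sidechain
    residues:
    - chain: A
      resno: 58.0
    - chain: A
      resno: 103.0
gates:
- label: ic_tyr_glu
  selA:
    chain: A
    resno: 5
    atoms: OH
    class: ALL
    hetero: ~
  selB:
    chain: A
    resno: 158
    atoms: OE1
    class: ALL
    hetero: ~
- label: ec_arg_glu
  selA:
    chain: A
    resno: 18
    atoms: NH1
    class: ALL
    hetero: ~
  selB:
    chain: A
    resno: 183
    atoms: OE2
    class: ALL
    hetero: ~
groups:
  extracellular:
    scaffold:
    - tm: TM3
      end: C_terminal
    - tm: TM5
      end: C_terminal
    - tm: TM9
      end: C_terminal
    - tm: TM4
      end: N_terminal
    - tm: TM8
      end: N_terminal
    - tm: TM10
      end: N_terminal
    bundle:
    - tm: TM1b
      end: C_terminal
    - tm: TM7
      end: C_terminal
    - tm: TM2
      end: N_terminal
    - tm: TM6a
      end: N_terminal
  intracellular:
    scaffold:
    - tm: TM3
      end: N_terminal
    - tm: TM5
      end: N_terminal
    - tm: TM9
      end: N_terminal
    - tm: TM4
      end: C_terminal
    - tm: TM8
      end: C_terminal
    - tm: TM10
      end: C_terminal
    bundle:
    - tm: TM1a
      end: N_terminal
    - tm: TM7
      end: N_terminal
    - tm: TM2
      end: C_terminal
    - tm: TM6b
      end: C_terminal
ion:
  chain: A
  resno: 901
  atoms: NA
  class: ALL
  hetero: yes
ligand:
  chain: A
  resno: 900
  atoms: ~
  class: ALL
  hetero: yes
sasa:
  probe: 1.4
  n_points: 960.0
  default_radius: 1.7
classification: {}
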