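schema_version: 1
thermostat_T: 298.0
exchange_stride: 1000
steps: 0
seed: 1
replicas:
- index: 0
  main_cvs:
  - z
  - COS
  aux_rosters: []
  multithermal_Tmax: ~
- index: 1
  main_cvs:
  - z
  - COS
  aux_rosters:
  - - WL4
    - t2
    - t3
  multithermal_Tmax: ~
- index: 2
  main_cvs:
  - z
  - COS
  aux_rosters:
  - - WL4
    - t2
    - t3
  - - WH1
    - t3
    - t1
  multithermal_Tmax: ~
- index: 3
  main_cvs:
  - z
  - COS
  aux_rosters:
  - - WL4
    - t2
    - t3
  - - WH1
    - t3
    - t1
  - - WL1
    - t1
    - t2
  multithermal_Tmax: ~
- index: 4
  main_cvs:
  - z
  - COS
  aux_rosters:
  - - WL4
    - t2
    - t3
  - - WH1
    - t3
    - t1
  - - WL1
    - t1
    - t2
  - - WH3
    - t2
    - t3
  multithermal_Tmax: 310.0
- index: 5
  main_cvs:
  - z
  - COS
  aux_rosters:
  - - WL4
    - t2
    - t3
  - - WH1
    - t3
    - t1
  - - WL1
    - t1
    - t2
  - - WH3
    - t2
    - t3
  - - WH8
    - t3
    - t1
  multithermal_Tmax: 330.0
- index: 6
  main_cvs:
  - z
  - COS
  aux_rosters:
  - - WL4
    - t2
    - t3
  - - WH1
    - t3
    - t1
  - - WL1
    - t1
    - t2
  - - WH3
    - t2
    - t3
  - - WH8
    - t3
    - t1
  - - WH5
    - t1
    - t2
  multithermal_Tmax: 350.0
- index: 7
  main_cvs:
  - z
  - COS
  aux_rosters:
  - - WL4
    - t2
    - t3
  - - WH1
    - t3
    - t1
  - - WL1
    - t1
    - t2
  - - WH3
    - t2
    - t3
  - - WH8
    - t3
    - t1
  - - WH5
    - t1
    - t2
  - - WH10
    - t2
    - t3
  multithermal_Tmax: 370.0
cv_specs:
- kind: z_projection
  label: z
  atom_selector:
  - 1
  - 2
  - 3
  - 4
  - 5
  period: 0.0
  point: ~
  params: ~
- kind: cos_orientation
  label: COS
  atom_selector:
  - 1
  - 5
  period: 0.0
  point: ~
  params: ~
- kind: torsion
  label: t1
  atom_selector:
  - 1
  - 2
  - 3
  - 4
  period: 6.2831853
  point: ~
  params: ~
- kind: torsion
  label: t2
  atom_selector:
  - 2
  - 3
  - 4
  - 5
  period: 6.2831853
  point: ~
  params: ~
- kind: torsion
  label: t3
  atom_selector:
  - 3
  - 4
  - 5
  - 6
  period: 6.2831853
  point: ~
  params: ~
- kind: coordination_WL
  label: WL4
  atom_selector:
  - 2
  period: 0.0
  point: ~
  params:
    r0: 0.25
    d_max: 0.08
    r_nl: 0.15
    'n': 6
    m: 10
    nl_update_stride: 20
- kind: coordination_WL
  label: WL1
  atom_selector:
  - 2
  period: 0.0
  point: ~
  params:
    r0: 0.25
    d_max: 0.08
    r_nl: 0.15
    'n': 6
    m: 10
    nl_update_stride: 20
- kind: coordination_WH
  label: WH1
  atom_selector: []
  period: 0.0
  point:
  - 0.0
  - 0.0
  - 0.1
  params:
    r0: 0.25
    d_max: 0.08
    r_nl: 0.15
    'n': 2
    m: 6
    nl_update_stride: 20
- kind: coordination_WH
  label: WH3
  atom_selector: []
  period: 0.0
  point:
  - 0.0
  - 0.0
  - 0.1
  params:
    r0: 0.25
    d_max: 0.08
    r_nl: 0.15
    'n': 2
    m: 6
    nl_update_stride: 20
- kind: coordination_WH
  label: WH8
  atom_selector: []
  period: 0.0
  point:
  - 0.0
  - 0.0
  - 0.1
  params:
    r0: 0.25
    d_max: 0.08
    r_nl: 0.15
    'n': 2
    m: 6
    nl_update_stride: 20
- kind: coordination_WH
  label: WH5
  atom_selector: []
  period: 0.0
  point:
  - 0.0
  - 0.0
  - 0.1
  params:
    r0: 0.25
    d_max: 0.08
    r_nl: 0.15
    'n': 2
    m: 6
    nl_update_stride: 20
- kind: coordination_WH
  label: WH10
  atom_selector: []
  period: 0.0
  point:
  - 0.0
  - 0.0
  - 0.1
  params:
    r0: 0.25
    d_max: 0.08
    r_nl: 0.15
    'n': 2
    m: 6
    nl_update_stride: 20
funnel:
  origin:
  - 0.0
  - 0.0
  - 0.0
  axis:
  - 0.0
  - 0.0
  - 1.0
  cylinder_radius: 0.2
  cone_half_angle: 0.6
  cone_to_cylinder_z: 0.4
  wall_spring_constant: 1000.0
  dual: yes
barrier_main: 100.0
barrier_multicv: 3.0
pace_main: 10000
pace_multicv: 20000
pace_multithermal: 100
n_temps: 8
sigma:
  z: 0.05
  COS: 0.1
sigma_source: ~

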