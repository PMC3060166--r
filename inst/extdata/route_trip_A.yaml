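format: antnav-scenario-1
name: route_trip_A
nest:
- 0.0
- 0.0
food:
  A:
    pos:
    - 350.0
    - 250.0
    has_food: yes
  B:
    pos:
    - 350.0
    - -250.0
    has_food: yes
landmarks:
- kind: route
  id: rA_out1
  center:
  - 122.099999999999994
  - 87.200000000000003
  radius: 20.0
  local_angle: -0.10764254587604
  gate_source: A
  gate_direction: outbound
- kind: route
  id: rA_out2
  center:
  - 235.0
  - 75.0
  radius: 20.0
  local_angle: 0.321750554396642
  gate_source: A
  gate_direction: outbound
- kind: route
  id: rA_out3
  center:
  - 340.0
  - 110.0
  radius: 20.0
  local_angle: 1.499488862009606
  gate_source: A
  gate_direction: outbound
- kind: route
  id: rA_in1
  center:
  - 250.0
  - 220.0
  radius: 20.0
  local_angle: -2.677945044588987
  gate_source: A
  gate_direction: inbound
- kind: route
  id: rA_in2
  center:
  - 150.0
  - 170.0
  radius: 20.0
  local_angle: -2.414950312908068
  gate_source: A
  gate_direction: inbound
- kind: route
  id: rA_in3
  center:
  - 60.0
  - 90.0
  radius: 20.0
  local_angle: -2.158798930342464
  gate_source: A
  gate_direction: inbound
- kind: route
  id: rB_out1
  center:
  - 150.0
  - -260.0
  radius: 20.0
  local_angle: -0.380506377112365
  gate_source: B
  gate_direction: outbound
- kind: route
  id: rB_out2
  center:
  - 250.0
  - -300.0
  radius: 20.0
  local_angle: 0.141897054604164
  gate_source: B
  gate_direction: outbound
- kind: route
  id: rB_out3
  center:
  - 320.0
  - -290.0
  radius: 20.0
  local_angle: 0.927295218001612
  gate_source: B
  gate_direction: outbound
- kind: route
  id: rB_in1
  center:
  - 210.0
  - -150.0
  radius: 20.0
  local_angle: -2.927531970025972
  gate_source: B
  gate_direction: inbound
- kind: route
  id: rB_in2
  center:
  - -20.0
  - -200.0
  radius: 20.0
  local_angle: 1.471127674303735
  gate_source: B
  gate_direction: inbound
- kind: route
  id: rB_in3
  center:
  - 120.0
  - -60.0
  radius: 20.0
  local_angle: 2.677945044588987
  gate_source: B
  gate_direction: inbound
- kind: place
  id: fLMA
  goal:
  - 350.0
  - 250.0
  radius: 25.0
  signposts:
  - - 401.96152422706632
    - 280.0
  - - 298.03847577293368
    - 280.0
  - - 350.0
    - 190.0
  learned:
  - - 51.96152422706632
    - 30.0
  - - -51.96152422706632
    - 30.0
  - - 0.0
    - -60.0
  gate_source: A
  gate_direction: outbound
- kind: place
  id: fLMB
  goal:
  - 350.0
  - -250.0
  radius: 25.0
  signposts:
  - - 401.96152422706632
    - -220.0
  - - 298.03847577293368
    - -219.999999999999972
  - - 350.0
    - -310.0
  learned:
  - - 51.96152422706632
    - 30.0
  - - -51.96152422706632
    - 30.000000000000028
  - - 0.0
    - -60.0
  gate_source: B
  gate_direction: outbound
- kind: place
  id: hLM
  goal:
  - 0.0
  - 0.0
  radius: 25.0
  signposts:
  - - 51.96152422706632
    - 29.999999999999996
  - - -51.961524227066306
    - 30.000000000000021
  - - -1.102182119232618e-14
    - -6.0e+01
  learned:
  - - 51.96152422706632
    - 29.999999999999996
  - - -51.961524227066306
    - 30.000000000000021
  - - -1.102182119232618e-14
    - -6.0e+01
  gate_source: ~
  gate_direction: inbound
memories:
  A:
    angle: 0.620249485982821
    length: 430.116263352131341
  B:
    angle: -0.620249485982821
    length: 430.116263352131341
target: A
weights:
  habituation: no
  hab_alpha: 0.03
  hab_beta: 0.03
  acs_off_gain: 2.0
  relax_rate: 0.5
weights_matrix:
- - 1.0
  - -1.2
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
- - -1.2
  - 1.0
  - 0.1
  - 0.1
  - 0.1
  - 0.1
  - 0.1
  - 0.1
- - 0.0
  - 0.3
  - 0.8
  - -1.2
  - 0.0
  - 0.0
  - 0.0
  - 0.0
- - 0.0
  - 0.3
  - -1.2
  - 0.8
  - 0.0
  - 0.0
  - 0.0
  - 0.0
- - 0.0
  - 0.3
  - 0.0
  - 0.0
  - 0.8
  - -1.2
  - 0.0
  - 0.0
- - 0.0
  - 0.3
  - 0.0
  - 0.0
  - -1.2
  - 0.8
  - 0.0
  - 0.0
- - 0.0
  - 0.3
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -1.2
- - 0.0
  - 0.3
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - -1.2
  - 0.0
arbitration:
  b: -0.4
  pi_acs_scale: 0.2
  eps: 1.0e-09
  eps_dir: 1.0e-09
acs:
  turn_min: -0.3
  turn_max: 0.7
  d1_0: 3.3
  d2_0: 20.0
  d1_max: 33.0
  d2_max: 200.0
  t_max: 500.0
agent:
  start:
  - 0.0
  - 0.0
  heading: 0.0
  current:
  - 0.0
  - 0.0
  motivation:
    forage: 1.0
    sourceA: 1.0
    outbound: 1.0
interventions: []
eps_goal: 10.0
step_length: 10.0
eps_pi: 1.0
gate_threshold: 0.5
max_steps: 400
seed: 1
stop_at_home: yes
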