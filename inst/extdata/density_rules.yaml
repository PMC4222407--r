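# Spatial conductance-density rules (pS/um^2), one block per channel per
# region, mirroring the model's membrane composition:
#   axon : Na_x 3500 uniform, K_V 40, K_M 50
#   soma : Na 420, Na_P 10, K_V 20, K_M 10, K_BK 0.6, K_AP 150, Ca_HVA 2,
#          HCN 0.95 (split 2/3 HCN1 : 1/3 HCN2)
#   dendrites: Na linear (apical 350 proximal -> 320 distal; basal 150 -> x0.5),
#          A-type total with proximal->distal variant exchange over 300 um
#          (apical total 300; basal 150 -> x1.7), K_V exponential decay
#          (start 20, lambda 80), K_M 5 on the proximal 100 um (apical) /
#          20 um (basal), K_BK 0.6, Ca_HVA 2, Ca_IT2 0.5 beyond 300 um,
#          HCN exponential growth from 0.95 with lambda 323 capped at 40x.
#
# `calibration` holds global per-channel scale factors used to match the
# control excitability targets (rheobase ~304 pA, F-I gain ~74.4 Hz/nA);
# they are restricted to Na-family and K_V conductances and to +/-30%.
calibration:
  Na: 1.0
  Na_x: 1.0
  K_V: 1.3

rules:
  - {channel: Na_x, region: axon, profile: uniform, start: 3500}
  - {channel: K_V, region: axon, profile: uniform, start: 40}
  - {channel: K_M, region: axon, profile: uniform, start: 50}

  - {channel: Na, region: soma, profile: uniform, start: 420}
  - {channel: Na_P, region: soma, profile: uniform, start: 10}
  - {channel: K_V, region: soma, profile: uniform, start: 20}
  - {channel: K_M, region: soma, profile: uniform, start: 10}
  - {channel: K_BK, region: soma, profile: uniform, start: 0.6}
  - {channel: K_A, region: soma, profile: linear_exchange, start: 150, end: 150, span: 300}
  - {channel: Ca_HVA, region: soma, profile: uniform, start: 2}
  - {channel: HCN, region: soma, profile: uniform, start: 0.95}

  - {channel: Na, region: apical, profile: linear, start: 350, end: 320}
  - {channel: K_A, region: apical, profile: linear_exchange, start: 300, end: 300, span: 300}
  - {channel: K_V, region: apical, profile: exponential, direction: decay, start: 20, length_constant: 80}
  - {channel: K_M, region: apical, profile: uniform, start: 5, max_distance: 100}
  - {channel: K_BK, region: apical, profile: uniform, start: 0.6}
  - {channel: Ca_HVA, region: apical, profile: uniform, start: 2}
  - {channel: Ca_IT2, region: apical, profile: uniform, start: 0.5, min_distance: 300}
  - {channel: HCN, region: apical, profile: exponential, direction: growth, start: 0.95, length_constant: 323, cap_factor: 40}

  - {channel: Na, region: basal, profile: linear, start: 150, end_factor: 0.5}
  - {channel: K_A, region: basal, profile: linear_exchange, start: 150, end_factor: 1.7, span: 300}
  - {channel: K_V, region: basal, profile: exponential, direction: decay, start: 20, length_constant: 80}
  - {channel: K_M, region: basal, profile: uniform, start: 5, max_distance: 20}
  - {channel: K_BK, region: basal, profile: uniform, start: 0.6}
  - {channel: Ca_HVA, region: basal, profile: uniform, start: 2}
  - {channel: Ca_IT2, region: basal, profile: uniform, start: 0.5, min_distance: 300}
  - {channel: HCN, region: basal, profile: exponential, direction: growth, start: 0.95, length_constant: 323, cap_factor: 40}
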