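# Stylized layer 5 pyramidal cell geometry (dimensions in micrometres).
# Sections are straight cables discretized into <= 20 um electrical
# compartments by make_reference_morphology(). Directions are unit-free
# vectors fixing the 3-D layout (apical +y, axon -y, basals oblique).
sections:
  - name: soma
    region: soma
    length: 23
    diam_start: 23
    direction: [0, 1, 0]
  - name: axon_hillock
    region: axon
    parent: soma
    length: 15
    diam_start: 2.2
    diam_end: 1.5
    direction: [0, -1, 0]
  - name: axon_initial_segment
    region: axon
    parent: axon_hillock
    length: 45
    diam_start: 1.3
    direction: [0, -1, 0]
  - name: axon_main
    region: axon
    parent: axon_initial_segment
    length: 140
    diam_start: 1.1
    direction: [0, -1, 0]
  - name: apical_trunk
    region: apical
    parent: soma
    length: 650
    diam_start: 4.5
    diam_end: 2.5
    direction: [0, 1, 0]
  - name: apical_tuft_a
    region: apical
    parent: apical_trunk
    length: 280
    diam_start: 1.6
    direction: [-0.45, 0.89, 0]
  - name: apical_tuft_b
    region: apical
    parent: apical_trunk
    length: 280
    diam_start: 1.6
    direction: [0.45, 0.89, 0]
  - name: basal_a
    region: basal
    parent: soma
    length: 190
    diam_start: 1.4
    direction: [-0.80, -0.60, 0]
  - name: basal_b
    region: basal
    parent: soma
    length: 190
    diam_start: 1.4
    direction: [0.80, -0.60, 0]
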