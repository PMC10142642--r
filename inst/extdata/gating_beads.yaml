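gates:
- id: g_accudrop_hi_b610
  type: rectangle
  channel_x: B610
  channel_y: B530
  transform_x: log10
  transform_y: log10
  xmin: 30000.0
  xmax: 1.0e+09
  ymin: 0.001
  ymax: 1.0e+09
- id: g_size_beads
  type: rectangle
  channel_x: B610
  channel_y: B530
  transform_x: log10
  transform_y: log10
  xmin: 0.001
  xmax: 30000.0
  ymin: 0.001
  ymax: 1.0e+09
- id: g_accudrop_cleanup
  type: rectangle
  channel_x: B530
  channel_y: SSC-A
  transform_x: log10
  transform_y: linear
  xmin: 0.001
  xmax: 3000.0
  ymin: 0.0
  ymax: 1.0e+09
- id: g_small_beads
  type: rectangle
  channel_x: B530
  channel_y: YG610
  transform_x: log10
  transform_y: log10
  xmin: 0.001
  xmax: 3000.0
  ymin: 0.001
  ymax: 1.0e+09
- id: g_3um
  type: rectangle
  channel_x: YG610
  channel_y: B530
  transform_x: log10
  transform_y: log10
  xmin: 0.001
  xmax: 3000.0
  ymin: 0.001
  ymax: 1.0e+09
- id: g_7um
  type: rectangle
  channel_x: YG610
  channel_y: B530
  transform_x: log10
  transform_y: log10
  xmin: 3000.0
  xmax: 1.0e+09
  ymin: 0.001
  ymax: 1.0e+09
- id: g_large_beads
  type: rectangle
  channel_x: B530
  channel_y: YG610
  transform_x: log10
  transform_y: log10
  xmin: 3000.0
  xmax: 1.0e+09
  ymin: 0.001
  ymax: 1.0e+09
- id: g_10um
  type: rectangle
  channel_x: B530
  channel_y: FSC-A
  transform_x: log10
  transform_y: linear
  xmin: 3000.0
  xmax: 30000.0
  ymin: 0.0
  ymax: 1.0e+09
- id: g_15um
  type: rectangle
  channel_x: B530
  channel_y: FSC-A
  transform_x: log10
  transform_y: linear
  xmin: 30000.0
  xmax: 260000.0
  ymin: 0.0
  ymax: 1.0e+09
- id: g_20um
  type: rectangle
  channel_x: B530
  channel_y: FSC-A
  transform_x: log10
  transform_y: linear
  xmin: 260000.0
  xmax: 1.0e+09
  ymin: 0.0
  ymax: 1.0e+09
tree:
- id: accudrop_hi
  parent: root
  gate: g_accudrop_hi_b610
- id: accudrop
  parent: accudrop_hi
  gate: g_accudrop_cleanup
  label: accudrop
- id: beads
  parent: root
  gate: g_size_beads
- id: small
  parent: beads
  gate: g_small_beads
- id: bead_3um
  parent: small
  gate: g_3um
  label: bead_3um
- id: bead_7um
  parent: small
  gate: g_7um
  label: bead_7um
- id: large
  parent: beads
  gate: g_large_beads
- id: bead_10um
  parent: large
  gate: g_10um
  label: bead_10um
- id: bead_15um
  parent: large
  gate: g_15um
  label: bead_15um
- id: bead_20um
  parent: large
  gate: g_20um
  label: bead_20um
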