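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
- id: g_not_accudrop
  type: rectangle
  channel_x: B610
  channel_y: B530
  transform_x: log10
  transform_y: log10
  xmin: 0.001
  xmax: 30000.0
  ymin: 0.001
  ymax: 1.0e+09
- id: g_wbc
  type: rectangle
  channel_x: R670
  channel_y: SSC-A
  transform_x: log10
  transform_y: linear
  xmin: 3000.0
  xmax: 1.0e+09
  ymin: 0.0
  ymax: 1.0e+09
- id: g_cd45_neg
  type: rectangle
  channel_x: R670
  channel_y: SSC-A
  transform_x: log10
  transform_y: linear
  xmin: 0.001
  xmax: 3000.0
  ymin: 0.0
  ymax: 1.0e+09
- id: g_rbc
  type: rectangle
  channel_x: B530
  channel_y: SSC-A
  transform_x: log10
  transform_y: linear
  xmin: 0.001
  xmax: 3000.0
  ymin: 0.0
  ymax: 1.0e+09
- id: g_spiked_beads
  type: rectangle
  channel_x: B530
  channel_y: SSC-A
  transform_x: log10
  transform_y: linear
  xmin: 3000.0
  xmax: 1.0e+09
  ymin: 0.0
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
- id: cells_beads
  parent: root
  gate: g_not_accudrop
- id: WBC
  parent: cells_beads
  gate: g_wbc
  label: WBC
- id: cd45neg
  parent: cells_beads
  gate: g_cd45_neg
- id: RBC
  parent: cd45neg
  gate: g_rbc
  label: RBC
- id: beads
  parent: cd45neg
  gate: g_spiked_beads
- id: bead_10um
  parent: beads
  gate: g_10um
  label: bead_10um
- id: bead_15um
  parent: beads
  gate: g_15um
  label: bead_15um
- id: bead_20um
  parent: beads
  gate: g_20um
  label: bead_20um
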