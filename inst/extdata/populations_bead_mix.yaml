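populations:
- name: bead_3um
  kind: bead
  diameter_um: 3.0
  concentration_per_ml: 4130000.0
  doublet_fraction: 0.05
  doublet_area_scale: 2.0
  doublet_height_scale: 1.2
  channels:
    FSC-A:
      median: 4500.0
      cv: 0.35
    FSC-H:
      median: 4500.0
      cv: 0.05
    SSC-A:
      median: 1350.0
      cv: 0.35
    SSC-H:
      median: 1350.0
      cv: 0.05
    B530:
      median: 400.0
      cv: 0.25
    YG610:
      median: 250.0
      cv: 0.25
    B610:
      median: 200.0
      cv: 0.25
    R670:
      median: 150.0
      cv: 0.25
- name: bead_7um
  kind: bead
  diameter_um: 7.0
  concentration_per_ml: 286000.0
  doublet_fraction: 0.05
  doublet_area_scale: 2.0
  doublet_height_scale: 1.2
  channels:
    FSC-A:
      median: 24500.0
      cv: 0.35
    FSC-H:
      median: 24500.0
      cv: 0.05
    SSC-A:
      median: 7350.0
      cv: 0.35
    SSC-H:
      median: 7350.0
      cv: 0.05
    B530:
      median: 400.0
      cv: 0.25
    YG610:
      median: 30000.0
      cv: 0.25
    B610:
      median: 200.0
      cv: 0.25
    R670:
      median: 150.0
      cv: 0.25
- name: bead_10um
  kind: bead
  diameter_um: 10.0
  concentration_per_ml: 161000.0
  doublet_fraction: 0.05
  doublet_area_scale: 2.0
  doublet_height_scale: 1.2
  channels:
    FSC-A:
      median: 50000.0
      cv: 0.35
    FSC-H:
      median: 50000.0
      cv: 0.05
    SSC-A:
      median: 15000.0
      cv: 0.35
    SSC-H:
      median: 15000.0
      cv: 0.05
    B530:
      median: 8000.0
      cv: 0.25
    YG610:
      median: 800.0
      cv: 0.25
    B610:
      median: 200.0
      cv: 0.25
    R670:
      median: 150.0
      cv: 0.25
- name: bead_15um
  kind: bead
  diameter_um: 15.0
  concentration_per_ml: 51000.0
  doublet_fraction: 0.05
  doublet_area_scale: 2.0
  doublet_height_scale: 1.2
  channels:
    FSC-A:
      median: 112500.0
      cv: 0.35
    FSC-H:
      median: 112500.0
      cv: 0.05
    SSC-A:
      median: 33750.0
      cv: 0.35
    SSC-H:
      median: 33750.0
      cv: 0.05
    B530:
      median: 80000.0
      cv: 0.25
    YG610:
      median: 800.0
      cv: 0.25
    B610:
      median: 200.0
      cv: 0.25
    R670:
      median: 150.0
      cv: 0.25
- name: bead_20um
  kind: bead
  diameter_um: 20.0
  concentration_per_ml: 25000.0
  doublet_fraction: 0.05
  doublet_area_scale: 2.0
  doublet_height_scale: 1.2
  channels:
    FSC-A:
      median: 200000.0
      cv: 0.35
    FSC-H:
      median: 200000.0
      cv: 0.05
    SSC-A:
      median: 60000.0
      cv: 0.35
    SSC-H:
      median: 60000.0
      cv: 0.05
    B530:
      median: 600000.0
      cv: 0.25
    YG610:
      median: 800.0
      cv: 0.25
    B610:
      median: 200.0
      cv: 0.25
    R670:
      median: 150.0
      cv: 0.25
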