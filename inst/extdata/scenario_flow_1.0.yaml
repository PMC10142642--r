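flow_rate_ml_min: 1.0
f_inner: 0.3333333
p_inner:
- population: bead_3um
  class: singlet
  p_inner: 0.1
- population: bead_3um
  class: doublet
  p_inner: 0.1
- population: bead_7um
  class: singlet
  p_inner: 0.15
- population: bead_7um
  class: doublet
  p_inner: 0.15
- population: bead_10um
  class: singlet
  p_inner: 0.55
- population: bead_10um
  class: doublet
  p_inner: 0.6
- population: bead_15um
  class: singlet
  p_inner: 0.98
- population: bead_15um
  class: doublet
  p_inner: 0.88
- population: bead_20um
  class: singlet
  p_inner: 0.995
- population: bead_20um
  class: doublet
  p_inner: 0.995
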