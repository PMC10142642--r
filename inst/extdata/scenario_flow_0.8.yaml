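flow_rate_ml_min: 0.8
f_inner: 0.3333333
p_inner:
- population: bead_3um
  class: singlet
  p_inner: 0.05
- population: bead_3um
  class: doublet
  p_inner: 0.05
- population: bead_7um
  class: singlet
  p_inner: 0.08
- population: bead_7um
  class: doublet
  p_inner: 0.08
- population: bead_10um
  class: singlet
  p_inner: 0.2
- population: bead_10um
  class: doublet
  p_inner: 0.25
- population: bead_15um
  class: singlet
  p_inner: 0.985
- population: bead_15um
  class: doublet
  p_inner: 0.85
- population: bead_20um
  class: singlet
  p_inner: 0.995
- population: bead_20um
  class: doublet
  p_inner: 0.995
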