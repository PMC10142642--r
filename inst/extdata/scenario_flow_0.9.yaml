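flow_rate_ml_min: 0.9
f_inner: 0.3333333
p_inner:
- population: bead_3um
  class: singlet
  p_inner: 0.08
- population: bead_3um
  class: doublet
  p_inner: 0.08
- population: bead_7um
  class: singlet
  p_inner: 0.12
- population: bead_7um
  class: doublet
  p_inner: 0.12
- population: bead_10um
  class: singlet
  p_inner: 0.463
- population: bead_10um
  class: doublet
  p_inner: 0.545
- population: bead_15um
  class: singlet
  p_inner: 0.985
- population: bead_15um
  class: doublet
  p_inner: 0.92
- population: bead_20um
  class: singlet
  p_inner: 0.995
- population: bead_20um
  class: doublet
  p_inner: 0.995
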