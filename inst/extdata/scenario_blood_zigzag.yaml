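flow_rate_ml_min: 0.8
f_inner: 0.3333333
p_inner:
- population: RBC
  class: singlet
  p_inner: 0.04
- population: RBC
  class: doublet
  p_inner: 0.04
- population: WBC
  class: singlet
  p_inner: 0.07
- population: WBC
  class: doublet
  p_inner: 0.07
- population: bead_10um
  class: singlet
  p_inner: 0.04
- population: bead_10um
  class: doublet
  p_inner: 0.12
- population: bead_15um
  class: singlet
  p_inner: 0.98
- population: bead_15um
  class: doublet
  p_inner: 0.95
- population: bead_20um
  class: singlet
  p_inner: 0.995
- population: bead_20um
  class: doublet
  p_inner: 0.995
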