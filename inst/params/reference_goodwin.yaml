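topology: goodwin
parameters:
  beta1: 0.02
  beta2: 20.0
  KA: 2.0
  m: 3.0
  deltaA: 0.063013380050904
  tau: 0.5
  pAT: 1.0
  nanodeg:
    kN: 12.0
    deltaN: 0.770163533955495
    kon: 0.3
    koff: 1.323
    pNT: 1.0
units: concentrations nM; time h; kon nM^-1 h^-1
notes: Calibrated synthetic reference set (not the published supplementary values).
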