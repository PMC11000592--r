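topology: activator_repressor
parameters:
  alpha1: 250.0
  alpha2: 1.0
  beta1: 0.04
  beta2: 1.0
  KA: 10.0
  KB: 26.0
  m: 2.0
  'n': 4.0
  k5: 30.0
  k6: 0.03
  deltaA: 0.173286795139986
  deltaB: 0.173286795139986
  pAT: 1.0
  pBT: 1.0
  nanodeg:
    kN: 8.0
    deltaN: 0.770163533955495
    kon: 3.0
    koff: 13.23
    pNT: 1.0
units: concentrations nM; time h; kon nM^-1 h^-1
notes: Calibrated synthetic reference set (not the published supplementary values).
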