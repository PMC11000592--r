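topology: mixed
parameters:
  k1: 10.0
  k2: 0.02
  k3: 5.0
  k4: 0.02
  k5: 5.0
  KA: 10.0
  KB: 10.0
  m: 10.0
  'n': 10.0
  deltaA: 0.063013380050904
  deltaB: 0.063013380050904
  deltaN: 0.770163533955495
  kon: 0.1
  koff: 0.441
  pAT: 1.0
  pBT: 1.0
  pNT: 22.399999999999999
units: concentrations nM; time h; kon nM^-1 h^-1
notes: Calibrated synthetic reference set (not the published supplementary values).
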