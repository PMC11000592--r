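topology: repressilator_common
parameters:
  k1: 4.0
  k2: 240.0
  k3: 4.0
  k4: 240.0
  k5: 4.0
  k6: 240.0
  KA: 8.0
  KB: 8.0
  KC: 8.0
  m: 4.0
  'n': 4.0
  r: 4.0
  deltaA: 0.173286795139986
  deltaB: 0.173286795139986
  deltaC: 0.173286795139986
  pAT: 1.0
  pBT: 1.0
  pCT: 1.0
  nanodeg:
    kN: 23.100000000000001
    deltaN: 0.770163533955495
    kon: 1.0
    koff: 4.41
    pNT: 1.0
units: concentrations nM; time h; kon nM^-1 h^-1
notes: Calibrated synthetic reference set (not the published supplementary values).
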