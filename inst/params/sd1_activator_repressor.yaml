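topology: activator_repressor
parameters:
  alpha1: ~
  alpha2: ~
  beta1: ~
  beta2: ~
  KA: ~
  KB: ~
  m: ~
  'n': ~
  k5: ~
  k6: ~
  deltaA: ~
  deltaB: ~
  pAT: ~
  pBT: ~
  nanodeg:
    kN: ~
    deltaN: ~
    kon: ~
    koff: ~
    pNT: ~
units: concentrations nM; time h; kon nM^-1 h^-1
notes: 'Transcription template: fill every slot with the published supplementary parameter
  values for this topology; half-lives must be converted to rates as ln(2)/t_half.'
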