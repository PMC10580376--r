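v_segments:
- id: TRBV1
  prefix: CASS
  prob: 0.2
- id: TRBV2
  prefix: CASR
  prob: 0.15
- id: TRBV3
  prefix: CAST
  prob: 0.15
- id: TRBV4
  prefix: CSAR
  prob: 0.12
- id: TRBV5
  prefix: CAWS
  prob: 0.12
- id: TRBV6
  prefix: CASQ
  prob: 0.1
- id: TRBV7
  prefix: CSVG
  prob: 0.08
- id: TRBV8
  prefix: CAIS
  prob: 0.08
j_segments:
- id: TRBJ1
  suffix: EQYF
  prob: 0.3
- id: TRBJ2
  suffix: YGYTF
  prob: 0.3
- id: TRBJ3
  suffix: ETQYF
  prob: 0.2
- id: TRBJ4
  suffix: NEQFF
  prob: 0.2
junction_length_dist:
  '4': 0.1
  '5': 0.18
  '6': 0.22
  '7': 0.2
  '8': 0.15
  '9': 0.1
  '10': 0.05
residue_dist:
  A: 0.074
  C: 0.025
  D: 0.054
  E: 0.054
  F: 0.047
  G: 0.074
  H: 0.026
  I: 0.068
  K: 0.058
  L: 0.099
  M: 0.025
  'N': 0.045
  P: 0.039
  Q: 0.034
  R: 0.052
  S: 0.057
  T: 0.051
  V: 0.073
  W: 0.013
  'Y': 0.032
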