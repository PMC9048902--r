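bead_types:
  name:
  - Q0
  - Qa
  - Na
  - C1
  - MW
  - EG
  mass:
  - 72.0
  - 72.0
  - 72.0
  - 72.0
  - 72.0
  - 44.0
  charge:
  - 1.0
  - -1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
pairs:
- types:
  - Q0-Q0
  - C1-C1
  sigma: 4.7
  epsilon: 0.836521
- types:
  - Qa-Qa
  - Qa-EG
  - MW-MW
  sigma: 4.7
  epsilon: 1.19503
- types:
  - Na-Na
  - Q0-Na
  - Qa-Na
  - Q0-EG
  sigma: 4.7
  epsilon: 0.956024
- types: EG-EG
  sigma: 4.3
  epsilon: 0.806644
- types: Q0-Qa
  sigma: 4.7
  epsilon: 1.075527
- types:
  - Q0-C1
  - Qa-C1
  sigma: 6.2
  epsilon: 0.478012
- types: MW-C1
  sigma: 4.7
  epsilon: 0.478012
- types:
  - Na-C1
  - EG-C1
  sigma: 4.7
  epsilon: 0.645316
- types:
  - Q0-MW
  - Qa-MW
  sigma: 4.7
  epsilon: 1.338434
- types: Na-MW
  sigma: 4.7
  epsilon: 0.956024
- types: EG-Na
  sigma: 4.7
  epsilon: 1.075527
- types: EG-MW
  sigma: 4.7
  epsilon: 1.075527
dihedral:
  phi0:
  - 180.0
  - 0.0
  - 0.0
  - 0.0
  K:
  - 0.46845
  - 0.046845
  - 0.078872
  - 0.028681
  'n':
  - 1.0
  - 2.0
  - 3.0
  - 4.0
bonded:
  bond_dppc:
    K: 24.0
    r0: 4.7
  bond_eg:
    K: 20.3
    r0: 3.3
  bond_graft:
    K: 203.0
    r0: 3.3
  angle_dppc:
    K: 3.0
    theta0_qana: 120.0
    theta0_other: 180.0
  angle_eg:
    K: 20.3
    theta0: 130.0
settings:
  cutoff: 12.0
  shift_onset: 9.0
  eps_r: 15.0
  solvent: explicit
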