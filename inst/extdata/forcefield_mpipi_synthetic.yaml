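name: mpipi-synthetic
provenance: synthetic
residues:
- code: A
  name: alanine
  charge: 0.0
  diameter: 5.04000000000000004
- code: R
  name: arginine
  charge: 1.0
  diameter: 6.55999999999999961
- code: 'N'
  name: asparagine
  charge: 0.0
  diameter: 5.67999999999999972
- code: D
  name: aspartate
  charge: -1.0
  diameter: 5.58000000000000007
- code: C
  name: cysteine
  charge: 0.0
  diameter: 5.48000000000000043
- code: Q
  name: glutamine
  charge: 0.0
  diameter: 6.01999999999999957
- code: E
  name: glutamate
  charge: -1.0
  diameter: 5.91999999999999993
- code: G
  name: glycine
  charge: 0.0
  diameter: 4.5
- code: I
  name: isoleucine
  charge: 0.0
  diameter: 6.17999999999999972
- code: L
  name: leucine
  charge: 0.0
  diameter: 6.17999999999999972
- code: K
  name: lysine
  charge: 1.0
  diameter: 6.36000000000000032
- code: M
  name: methionine
  charge: 0.0
  diameter: 6.17999999999999972
- code: F
  name: phenylalanine
  charge: 0.0
  diameter: 6.36000000000000032
- code: P
  name: proline
  charge: 0.0
  diameter: 5.55999999999999961
- code: S
  name: serine
  charge: 0.0
  diameter: 5.17999999999999972
- code: T
  name: threonine
  charge: 0.0
  diameter: 5.62000000000000011
- code: W
  name: tryptophan
  charge: 0.0
  diameter: 6.78000000000000025
- code: 'Y'
  name: tyrosine
  charge: 0.0
  diameter: 6.45999999999999996
- code: V
  name: valine
  charge: 0.0
  diameter: 5.86000000000000032
- code: H
  name: histidine (averaged)
  charge: 0.375
  diameter: 6.08000000000000007
epsilon:
- - A
  - A
  - 0.09
- - A
  - R
  - 0.10100000000000001
- - A
  - 'N'
  - 0.083
- - A
  - D
  - 0.074
- - A
  - C
  - 0.105
- - A
  - Q
  - 0.08400000000000001
- - A
  - E
  - 0.066
- - A
  - G
  - 0.089
- - A
  - I
  - 0.113
- - A
  - L
  - 0.11700000000000001
- - A
  - K
  - 0.064
- - A
  - M
  - 0.107
- - A
  - F
  - 0.14000000000000001
- - A
  - P
  - 0.10000000000000001
- - A
  - S
  - 0.083
- - A
  - T
  - 0.08500000000000001
- - A
  - W
  - 0.14499999999999999
- - A
  - 'Y'
  - 0.13700000000000001
- - A
  - V
  - 0.104
- - A
  - H
  - 0.098
- - R
  - R
  - 0.112
- - R
  - 'N'
  - 0.094
- - R
  - D
  - 0.08500000000000001
- - R
  - C
  - 0.11600000000000001
- - R
  - Q
  - 0.095
- - R
  - E
  - 0.077
- - R
  - G
  - 0.10000000000000001
- - R
  - I
  - 0.124
- - R
  - L
  - 0.128
- - R
  - K
  - 0.075
- - R
  - M
  - 0.11799999999999999
- - R
  - F
  - 0.47099999999999997
- - R
  - P
  - 0.111
- - R
  - S
  - 0.094
- - R
  - T
  - 0.096
- - R
  - W
  - 0.51439999999999997
- - R
  - 'Y'
  - 0.44240000000000002
- - R
  - V
  - 0.115
- - R
  - H
  - 0.109
- - 'N'
  - 'N'
  - 0.076
- - 'N'
  - D
  - 0.067
- - 'N'
  - C
  - 0.098
- - 'N'
  - Q
  - 0.077
- - 'N'
  - E
  - 0.059
- - 'N'
  - G
  - 0.082
- - 'N'
  - I
  - 0.106
- - 'N'
  - L
  - 0.11
- - 'N'
  - K
  - 0.057
- - 'N'
  - M
  - 0.10000000000000001
- - 'N'
  - F
  - 0.13300000000000001
- - 'N'
  - P
  - 0.093
- - 'N'
  - S
  - 0.076
- - 'N'
  - T
  - 0.078
- - 'N'
  - W
  - 0.13800000000000001
- - 'N'
  - 'Y'
  - 0.13
- - 'N'
  - V
  - 0.097
- - 'N'
  - H
  - 0.091
- - D
  - D
  - 0.058
- - D
  - C
  - 0.089
- - D
  - Q
  - 0.068
- - D
  - E
  - 0.05
- - D
  - G
  - 0.073
- - D
  - I
  - 0.097
- - D
  - L
  - 0.10100000000000001
- - D
  - K
  - 0.048
- - D
  - M
  - 0.091
- - D
  - F
  - 0.124
- - D
  - P
  - 0.08400000000000001
- - D
  - S
  - 0.067
- - D
  - T
  - 0.06900000000000001
- - D
  - W
  - 0.129
- - D
  - 'Y'
  - 0.121
- - D
  - V
  - 0.08799999999999999
- - D
  - H
  - 0.082
- - C
  - C
  - 0.12
- - C
  - Q
  - 0.099
- - C
  - E
  - 0.081
- - C
  - G
  - 0.104
- - C
  - I
  - 0.128
- - C
  - L
  - 0.13200000000000001
- - C
  - K
  - 0.079
- - C
  - M
  - 0.122
- - C
  - F
  - 0.155
- - C
  - P
  - 0.115
- - C
  - S
  - 0.098
- - C
  - T
  - 0.10000000000000001
- - C
  - W
  - 0.16
- - C
  - 'Y'
  - 0.152
- - C
  - V
  - 0.11899999999999999
- - C
  - H
  - 0.113
- - Q
  - Q
  - 0.078
- - Q
  - E
  - 0.06
- - Q
  - G
  - 0.083
- - Q
  - I
  - 0.107
- - Q
  - L
  - 0.111
- - Q
  - K
  - 0.058
- - Q
  - M
  - 0.10100000000000001
- - Q
  - F
  - 0.13400000000000001
- - Q
  - P
  - 0.094
- - Q
  - S
  - 0.077
- - Q
  - T
  - 0.079
- - Q
  - W
  - 0.13900000000000001
- - Q
  - 'Y'
  - 0.13100000000000001
- - Q
  - V
  - 0.098
- - Q
  - H
  - 0.092
- - E
  - E
  - 0.042
- - E
  - G
  - 0.065
- - E
  - I
  - 0.089
- - E
  - L
  - 0.093
- - E
  - K
  - 0.04
- - E
  - M
  - 0.083
- - E
  - F
  - 0.11600000000000001
- - E
  - P
  - 0.076
- - E
  - S
  - 0.059
- - E
  - T
  - 0.061
- - E
  - W
  - 0.121
- - E
  - 'Y'
  - 0.113
- - E
  - V
  - 0.08
- - E
  - H
  - 0.074
- - G
  - G
  - 0.08799999999999999
- - G
  - I
  - 0.112
- - G
  - L
  - 0.11600000000000001
- - G
  - K
  - 0.063
- - G
  - M
  - 0.106
- - G
  - F
  - 0.13900000000000001
- - G
  - P
  - 0.099
- - G
  - S
  - 0.082
- - G
  - T
  - 0.08400000000000001
- - G
  - W
  - 0.14399999999999999
- - G
  - 'Y'
  - 0.13600000000000001
- - G
  - V
  - 0.10299999999999999
- - G
  - H
  - 0.097
- - I
  - I
  - 0.13600000000000001
- - I
  - L
  - 0.14000000000000001
- - I
  - K
  - 0.08699999999999999
- - I
  - M
  - 0.13
- - I
  - F
  - 0.16300000000000001
- - I
  - P
  - 0.123
- - I
  - S
  - 0.106
- - I
  - T
  - 0.108
- - I
  - W
  - 0.16800000000000001
- - I
  - 'Y'
  - 0.16
- - I
  - V
  - 0.127
- - I
  - H
  - 0.121
- - L
  - L
  - 0.14399999999999999
- - L
  - K
  - 0.091
- - L
  - M
  - 0.13400000000000001
- - L
  - F
  - 0.16700000000000001
- - L
  - P
  - 0.127
- - L
  - S
  - 0.11
- - L
  - T
  - 0.112
- - L
  - W
  - 0.17199999999999999
- - L
  - 'Y'
  - 0.16400000000000001
- - L
  - V
  - 0.13100000000000001
- - L
  - H
  - 0.125
- - K
  - K
  - 0.038
- - K
  - M
  - 0.081
- - K
  - F
  - 0.23400000000000001
- - K
  - P
  - 0.074
- - K
  - S
  - 0.057
- - K
  - T
  - 0.059
- - K
  - W
  - 0.25340000000000001
- - K
  - 'Y'
  - 0.22140000000000001
- - K
  - V
  - 0.078
- - K
  - H
  - 0.07199999999999999
- - M
  - M
  - 0.124
- - M
  - F
  - 0.157
- - M
  - P
  - 0.11700000000000001
- - M
  - S
  - 0.10000000000000001
- - M
  - T
  - 0.10199999999999999
- - M
  - W
  - 0.16200000000000001
- - M
  - 'Y'
  - 0.154
- - M
  - V
  - 0.121
- - M
  - H
  - 0.115
- - F
  - F
  - 0.48999999999999999
- - F
  - P
  - 0.14999999999999999
- - F
  - S
  - 0.13300000000000001
- - F
  - T
  - 0.13500000000000001
- - F
  - W
  - 0.53100000000000003
- - F
  - 'Y'
  - 0.46300000000000002
- - F
  - V
  - 0.154
- - F
  - H
  - 0.42399999999999999
- - P
  - P
  - 0.11
- - P
  - S
  - 0.093
- - P
  - T
  - 0.095
- - P
  - W
  - 0.155
- - P
  - 'Y'
  - 0.14699999999999999
- - P
  - V
  - 0.114
- - P
  - H
  - 0.108
- - S
  - S
  - 0.076
- - S
  - T
  - 0.078
- - S
  - W
  - 0.13800000000000001
- - S
  - 'Y'
  - 0.13
- - S
  - V
  - 0.097
- - S
  - H
  - 0.091
- - T
  - T
  - 0.08
- - T
  - W
  - 0.14000000000000001
- - T
  - 'Y'
  - 0.13200000000000001
- - T
  - V
  - 0.099
- - T
  - H
  - 0.093
- - W
  - W
  - 0.57632000000000005
- - W
  - 'Y'
  - 0.50112000000000001
- - W
  - V
  - 0.159
- - W
  - H
  - 0.46211999999999998
- - 'Y'
  - 'Y'
  - 0.43791999999999998
- - 'Y'
  - V
  - 0.151
- - 'Y'
  - H
  - 0.39892
- - V
  - V
  - 0.11799999999999999
- - V
  - H
  - 0.112
- - H
  - H
  - 0.106
sigma_overrides: []
electrostatics:
  coulomb_constant: 332.0
  dielectric: 80.0
  salt_coefficient: 1.0
  reference_temperature: 300.0
  ionic_strength: 0.14999999999999999
bonded:
  k_bond: 20.0
  d0: 3.79999999999999982
  k_angle: 2.0
  theta0: 2.12000000000000011
  k_dihedral: 1.0
  phi0: -1.30000000000000004
cutoffs:
  contact_factor: 3.0
  electrostatic: 35.0
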