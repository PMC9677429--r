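# epmm pseudoatom databank
VERSION fixture-1
ENTRY H_O
KEY H O
PARAM 0.000000 0.660000 1.120000 1.180000
PLM 1 0 0.060000
RADIAL 2.000000 0 1 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY H_N
KEY H N
PARAM 0.000000 0.600000 1.120000 1.180000
PLM 1 0 0.060000
RADIAL 2.000000 0 1 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY H_C
KEY H C
PARAM 0.000000 0.950000 1.120000 1.180000
PLM 1 0 0.050000
RADIAL 2.000000 0 1 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY H_any
KEY H ANY
PARAM 0.000000 1.000000 1.100000 1.180000
RADIAL 2.000000 0 1 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY O_water
KEY O H H
PARAM 2.000000 6.680000 0.975000 1.100000
PLM 1 0 -0.060000
PLM 2 0 0.050000
RADIAL 2.226600 2 2 2 3 4
FRAME BISECT_Z
PROVENANCE synthetic fixture
ENTRY O_water_mg
KEY O H H MG
PARAM 2.000000 6.600000 0.975000 1.100000
PLM 1 0 0.050000
RADIAL 2.226600 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY O_P
KEY O P
PARAM 2.000000 6.700000 0.972000 1.100000
PLM 1 0 0.100000
PLM 2 0 -0.040000
RADIAL 2.226600 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY O_P_mg
KEY O MG P
PARAM 2.000000 6.650000 0.972000 1.100000
PLM 1 0 0.080000
RADIAL 2.226600 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY O_PP
KEY O P P
PARAM 2.000000 6.550000 0.975000 1.100000
PLM 1 0 -0.040000
RADIAL 2.226600 2 2 2 3 4
FRAME BISECT_Z
PROVENANCE synthetic fixture
ENTRY O_CP
KEY O C P
PARAM 2.000000 6.520000 0.975000 1.100000
PLM 1 0 -0.030000
RADIAL 2.226600 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY O_C
KEY O C
PARAM 2.000000 6.450000 0.972000 1.100000
PLM 1 0 0.120000
PLM 2 0 0.050000
RADIAL 2.226600 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY O_CH
KEY O C H
PARAM 2.000000 6.500000 0.975000 1.100000
PLM 1 0 0.080000
RADIAL 2.226600 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY O_any
KEY O ANY
PARAM 2.000000 6.000000 0.980000 1.100000
RADIAL 2.226600 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY N_CH3
KEY N C H H H
PARAM 2.000000 5.300000 0.990000 1.050000
PLM 1 0 -0.060000
RADIAL 1.917000 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY N_any
KEY N ANY
PARAM 2.000000 5.000000 0.990000 1.050000
RADIAL 1.917000 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY C_HHO
KEY C H H O
PARAM 2.000000 4.030000 0.990000 0.900000
PLM 1 0 0.080000
RADIAL 1.567900 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY C_HHN
KEY C H H N
PARAM 2.000000 4.050000 0.990000 0.900000
PLM 1 0 0.060000
RADIAL 1.567900 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY C_COO
KEY C C O O
PARAM 2.000000 3.800000 1.010000 0.900000
PLM 1 0 0.050000
PLM 2 0 0.100000
RADIAL 1.567900 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY C_CH3
KEY C C H H H
PARAM 2.000000 4.100000 0.990000 0.900000
PLM 1 0 0.030000
RADIAL 1.567900 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY C_any
KEY C ANY
PARAM 2.000000 4.000000 1.000000 0.900000
RADIAL 1.567900 2 2 2 3 4
FRAME ZX
PROVENANCE synthetic fixture
ENTRY P_O4
KEY P O O O O
PARAM 10.000000 3.600000 1.040000 1.000000
PLM 3 -2 0.100000
RADIAL 1.800000 2 2 4 6 8
FRAME ZX
PROVENANCE synthetic fixture
ENTRY P_any
KEY P ANY
PARAM 10.000000 5.000000 1.000000 1.000000
RADIAL 1.800000 2 2 4 6 8
FRAME ZX
PROVENANCE synthetic fixture
ENTRY S_CH
KEY S C H
PARAM 10.000000 6.050000 0.990000 1.000000
PLM 1 0 0.050000
PLM 2 0 -0.050000
RADIAL 1.827300 6 6 6 6 6
FRAME ZX
PROVENANCE synthetic fixture
ENTRY S_any
KEY S ANY
PARAM 10.000000 6.000000 0.990000 1.000000
RADIAL 1.827300 6 6 6 6 6
FRAME ZX
PROVENANCE synthetic fixture
ENTRY MG_any
KEY MG ANY
PARAM 10.000000 1.600000 1.100000 1.000000
RADIAL 1.102500 2 2 2 3 4
FRAME NONE
PROVENANCE synthetic fixture
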