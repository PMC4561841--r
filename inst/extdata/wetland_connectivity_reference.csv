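wetland,snow_category,area_m2,network,pc_pct,intra_pct,flux_pct,connector_pct
A,neutral,400,spatial,10.3,0.8,9.5,0
A,neutral,400,temporal,0.05,0.03,0.02,0
A,neutral,400,stepping_stone,2.09,1.93,0.158,0
B,neutral,3000,spatial,11.5,0.8,10.68,0.0218
B,neutral,3000,temporal,2.1,1.51,0.59,0
B,neutral,3000,stepping_stone,2.18,1.93,0.249,0.0004236
C,neutral,20000,spatial,2.15,0.03,2.11,0.0172
C,neutral,20000,temporal,68.47,67.14,1.32,0
C,neutral,20000,stepping_stone,0.105,0.0679,0.0373,0.0000236
D,neutral,10000,spatial,8.28,7.19,1.09,0
D,neutral,10000,temporal,16.79,16.79,0,0
D,neutral,10000,stepping_stone,17.4,17.4,0,0
E,low,1800,spatial,7.36,0.45,6.91,0.00153
E,low,1800,temporal,0.16,0.16,0,0
E,low,1800,stepping_stone,1.14,1.09,0.0528,0
F,low,4000,spatial,26.52,4.99,21.52,0.00445
F,low,4000,temporal,0.96,0.8,0.16,0.0000669
F,low,4000,stepping_stone,12.9,12.1,0.813,0.0000316
G,low,2000,spatial,5.51,0.16,5.28,0.0693
G,low,2000,temporal,0.35,0.2,0.15,0
G,low,2000,stepping_stone,1.14,0.391,0.748,0
H,high,8750,spatial,1.2,0.01,1.19,0
H,high,8750,temporal,2.75,2.66,0.1,0
H,high,8750,stepping_stone,0.47,0.0193,0.451,0
I,high,675,spatial,45.24,19.97,25.25,0.0166
I,high,675,temporal,0.11,0.02,0.1,0
I,high,675,stepping_stone,48.8,48.3,0.502,0
J,high,4000,spatial,4.49,0.2,4.29,0
J,high,4000,temporal,0.58,0.55,0.03,0
J,high,4000,stepping_stone,0.509,0.483,0.0262,0
K,high,1350,spatial,21.07,3.82,17.23,0.0122
K,high,1350,temporal,0.12,0.06,0.05,0
K,high,1350,stepping_stone,9.4,9.25,0.156,0
L,high,750,spatial,1.98,0.02,1.94,0.02
L,high,750,temporal,0.11,0.02,0.09,0.000209
L,high,750,stepping_stone,0.172,0.055,0.117,0.000355
M,high,6300,spatial,4.13,0.09,4.02,0.0137
M,high,6300,temporal,3.34,1.38,1.96,0
M,high,6300,stepping_stone,0.314,0.22,0.0938,0.0000119
N,high,700,spatial,5.84,1.98,3.86,0
N,high,700,temporal,0.02,0.02,0,0
N,high,700,stepping_stone,4.79,4.79,0.0000032,0
O,high,1000,spatial,1,0.02,0.97,0.00325
O,high,1000,temporal,0.05,0.03,0.02,0
O,high,1000,stepping_stone,0.103,0.0592,0.0439,0
P,high,200,spatial,1.34,0.05,1.29,0
P,high,200,temporal,0,0,0,0
P,high,200,stepping_stone,0.154,0.121,0.0332,0
Q,high,12000,spatial,0.29,0,0.29,0.00296
Q,high,12000,temporal,0.02,0.01,0.02,0.000185
Q,high,12000,stepping_stone,0.0303,0.00483,0.0254,0
R,high,450,spatial,1.4,0.01,1.37,0.0229
R,high,450,temporal,7.67,4.99,2.67,0
R,high,450,stepping_stone,0.094,0.0245,0.0694,0.00015
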