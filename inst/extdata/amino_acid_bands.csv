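amino_acid,center,hwhm,amplitude
A,1445,8,1.0
A,850,6,0.55
A,920,7,0.35
A,1110,8,0.30
A,1360,7,0.45
A,530,8,0.25
C,680,7,1.0
C,500,8,0.60
C,1395,8,0.40
C,1050,7,0.30
C,870,7,0.25
D,940,7,1.0
D,870,6,0.50
D,1415,8,0.45
D,1320,8,0.30
D,620,8,0.25
E,860,7,1.0
E,1420,8,0.50
E,1080,8,0.35
E,550,8,0.30
E,1350,8,0.25
F,1000,6,1.0
F,1033,6,0.75
F,1205,7,0.45
F,1585,7,0.40
F,620,7,0.35
F,830,7,0.25
G,1325,8,1.0
G,890,7,0.60
G,1440,8,0.35
G,1040,7,0.30
G,500,8,0.25
H,1575,7,1.0
H,1180,7,0.50
H,950,7,0.40
H,1090,8,0.30
H,620,8,0.30
I,1170,7,1.0
I,960,7,0.50
I,1455,8,0.40
I,835,7,0.35
I,1315,8,0.25
K,1050,7,1.0
K,1445,8,0.40
K,860,7,0.35
K,1320,8,0.30
K,745,7,0.25
L,1130,7,1.0
L,840,7,0.55
L,965,7,0.40
L,1340,8,0.35
L,530,8,0.25
M,720,7,1.0
M,655,7,0.60
M,1420,8,0.35
M,1015,7,0.30
M,870,7,0.25
N,1410,8,1.0
N,1115,7,0.60
N,775,7,0.40
N,1205,8,0.35
N,560,8,0.30
P,915,7,1.0
P,1450,8,0.40
P,1080,8,0.35
P,640,8,0.30
P,1195,7,0.25
Q,1090,8,1.0
Q,900,7,0.50
Q,1410,8,0.40
Q,650,8,0.30
Q,1195,7,0.30
R,790,7,1.0
R,1085,8,0.60
R,980,7,0.35
R,1180,8,0.30
R,640,8,0.25
S,830,7,1.0
S,975,7,0.45
S,1470,8,0.35
S,610,8,0.30
S,1125,8,0.25
T,605,7,1.0
T,930,7,0.50
T,1105,8,0.40
T,1455,8,0.30
T,770,7,0.25
V,1360,8,1.0
V,950,7,0.45
V,825,7,0.35
V,1135,8,0.30
V,540,8,0.25
W,1552,7,1.0
W,760,7,0.80
W,1012,6,0.45
W,875,7,0.40
W,1340,8,0.35
W,577,7,0.30
Y,1615,7,1.0
Y,845,7,0.60
Y,645,7,0.50
Y,1178,7,0.40
Y,985,7,0.30
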