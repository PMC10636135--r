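aa,chi1,chi2,chi3,chi4,prob
S,62,,,,0.48
S,-177,,,,0.22
S,-65,,,,0.30
C,-65,,,,0.50
C,-177,,,,0.26
C,62,,,,0.24
T,62,,,,0.49
T,-175,,,,0.07
T,-65,,,,0.44
V,175,,,,0.73
V,-60,,,,0.20
V,64,,,,0.07
I,-65,170,,,0.60
I,-65,-60,,,0.15
I,62,170,,,0.10
I,-177,170,,,0.15
L,-65,175,,,0.59
L,-177,65,,,0.29
L,-85,65,,,0.12
M,-65,-65,-70,,0.30
M,-177,180,75,,0.25
M,-65,180,180,,0.45
F,-65,90,,,0.44
F,-177,80,,,0.33
F,62,90,,,0.13
Y,-65,90,,,0.43
Y,-177,80,,,0.34
Y,62,90,,,0.13
W,-65,95,,,0.32
W,-177,-105,,,0.29
W,62,90,,,0.16
D,-70,-15,,,0.51
D,-177,0,,,0.29
D,62,-10,,,0.20
N,-65,-40,,,0.47
N,-177,-60,,,0.27
N,62,-75,,,0.26
E,-65,-65,-40,,0.34
E,-177,180,0,,0.27
E,-65,180,-10,,0.39
Q,-65,-65,-40,,0.36
Q,-177,65,0,,0.22
Q,-65,180,60,,0.42
K,-65,180,180,180,0.39
K,-177,180,180,180,0.28
K,-65,-65,180,180,0.18
K,62,180,180,180,0.15
R,-65,180,180,180,0.37
R,-177,180,180,-85,0.31
R,-65,-65,180,180,0.32
H,-65,-70,,,0.45
H,-177,65,,,0.31
H,62,-75,,,0.24
P,30,-40,,,0.56
P,-25,40,,,0.44
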