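# hydromorph van der Waals radius table, version 1
# Bondi-type heavy-atom radii (Angstrom) with implicit hydrogens;
# metals use conventional ionic/van der Waals compromise values.
element	radius
H	1.20
C	1.70
N	1.55
O	1.52
P	1.80
S	1.80
F	1.47
CL	1.75
BR	1.85
I	1.98
MG	1.73
NA	2.27
K	2.75
CA	2.31
MN	1.73
FE	1.70
ZN	1.39
CU	1.40
SE	1.90
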