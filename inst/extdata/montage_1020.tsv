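label	az_deg	polar_deg
Fp1	108	0
Fp2	72	0
F7	144	0
F3	129	30
Fz	90	45
F4	51	30
F8	36	0
T7	180	0
C3	180	45
Cz	0	90
C4	0	45
T8	0	0
P7	-144	0
P3	-129	30
Pz	-90	45
P4	-51	30
P8	-36	0
O1	-108	0
O2	-72	0
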