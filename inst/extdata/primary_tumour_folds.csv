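gene,cell_line_fold,korkola_fold,palmer_fold
EPCAM,561.2,0.4,0.4
TACSTD2,448.8,0.1,0.9
GGCT,120.4,1.0,1.5
F2RL1,106.1,0.9,0.8
TDRD12,84.4,8.5,8.0
FABP5,65.7,1.4,0.5
HSPA2,50.7,0.9,0.9
SOX17,48.7,0.8,0.6
RBMXL2,43.5,2.3,1.4
BASP1,42.0,0.8,1.3
DDX43,37.3,3.6,3.9
KLF4,29.9,5.9,7.2
LGALS3,28.1,0.8,1.6
ESRP2,27.7,0.3,0.5
CYB5R2,18.2,1.1,1.0
OXCT1,17.2,1.2,1.9
HIST1H4C,17.1,1.5,0.9
CLDN7,15.2,0.4,0.2
ALDH1A3,14.6,1.4,0.4
ECHDC3,14.5,0.9,1.8
TRIL,14.4,1.9,1.4
TMEM168,14.2,1.4,2.2
CXCL14,13.0,2.7,5.1
DSCR6,10.2,0.5,0.2
GPX7,9.6,1.0,1.0
FAM184A,9.4,0.4,0.5
ECHDC2,9.2,0.5,0.9
IER2,9.0,1.0,1.5
GUCA1A,7.5,1.8,1.2
LGALS8,7.4,0.6,0.9
ST14,6.7,0.7,0.5
MAPK13,6.3,0.5,0.8
LMO7,6.2,0.6,0.8
OVOL1,6.2,0.8,0.8
LY75,6.0,3.5,3.4
CYB5R1,5.6,1.0,1.3
GIPC2,5.6,0.6,0.8
EPS8L2,5.5,0.4,0.4
CST6,4.8,0.8,1.2
PKP3,4.7,0.4,0.3
ALX1,4.6,1.0,0.8
PARP12,4.3,3.9,2.6
BST1,4.3,1.5,1.5
CYP1B1,4.3,1.0,1.8
MNS1,3.6,1.0,1.0
SOX15,3.5,5.9,3.3
MTL5,3.5,0.8,0.8
MYD88,3.3,1.0,0.9
PRDM14,3.2,1.6,1.2
MEIS1,3.2,0.5,0.4
TNFRSF10C,3.1,0.9,1.0
TRIM25,3.1,1.0,0.9
PON3,3.0,1.6,4.9
PLXND1,3.0,1.0,0.9
RPRM,3.0,2.3,2.4
LTBP2,2.9,1.1,0.6
FUT1,2.8,1.1,1.0
SLC25A38,2.8,0.8,0.8
EPS8L1,2.6,0.8,0.7
ARPC1B,2.6,2.3,2.9
EDNRB,2.6,0.9,0.9
TEAD3,2.5,0.6,0.7
ACADL,2.5,1.1,0.9
TUBB6,2.5,0.9,0.6
ZMIZ1,2.4,1.6,1.1
ABHD14A,2.2,0.8,0.9
ELMO3,2.2,0.8,0.7
AMPD3,2.1,1.1,1.3
LRRFIP1,2.0,1.3,1.2
ZIC1,2.0,0.5,0.7
SH2D3A,1.6,1.0,1.0
NAAA,1.5,1.1,1.1
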