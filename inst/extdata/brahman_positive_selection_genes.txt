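BCL10
C1orf52
SYT10
ANXA5
BBS7
EXOSC9
STARD4
ACOT12
ANKRD34B
CKMT2
FAM151B
RASGRF2
SSBP2
CEP128
CYP26B1
DYSF
EMX1
EXOC6B
SPR
BIRC6
CRIM1
DPY30
MEMO1
NLRC4
SLC30A6
SPAST
TTC27
YIPF4
MAPKAP1
PBX3
NAA16
VWA8
AHCY
DYNLRB1
MAFB
MAP1LC3A
PIGU
TOP1
SDC2
SNTB1
ZNF648
TTC28
ABT1
HFE
PRSS16
SLC17A2
TRIM38
ZNF184
ZNF391
AQP8
LCMT1
SCNN1G
USP31
RAB11FIP2
ABCC2
CHUK
COX15
CPN1
CRTAC1
CUTC
DNMBP
ENTPD7
ERLIN1
SFRP5
SORCS1
ZFYVE27
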