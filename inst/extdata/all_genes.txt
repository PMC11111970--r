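ABL1
ATF7IP
BTG1
CDKN2A
CREBBP
CRLF2
CSF1R
DUX4
EBF1
EPOR
ERG
ETV6
FLT3
IGLL5
IKZF1
JAK2
KMT2A
KRAS
MEF2D
NFATC1
NR3C1
NRAS
NUTM1
P2RY8
PAX5
PBX1
PDGFRB
PTPN11
RB1
RUNX1
SH2B3
TBL1XR1
TCF3
VPREB1
ZNF384
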