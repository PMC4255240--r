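V1
V2
V3
V3A
V4
V4t
7A
7B
LIP
STPr
STPi
STPc
FST
MST
MT
TEpd
TEpv
TEad
TEav
TEa/ma
TEa/mp
8L
8m
TEO
TEOm
DP
V6
V6A
VIP
PIP
TF
TH
MIP
7m
9/46d
9/46v
46v
46d
PERIRHINAL
ENTORHINAL
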