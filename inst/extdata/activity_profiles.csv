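enzyme,time_hr,activity
PTA,0,1
PTA,1,1
PTA,2,1
PTA,3,1
PTA,4,1
PTA,5,1
PTA,6,1
PTA,7,1
PTA,8,0.4
PTA,9,0.4
PTA,10,0.4
PTA,11,0.4
PTA,12,0.4
PTA,13,0.4
PTA,14,0.4
PTA,15,0.4
PTA,16,0.28
PTA,17,0.28
PTA,18,0.28
PTA,19,0.28
PTA,20,0.28
PTA,21,0.28
PTA,22,0.28
PTA,23,0.28
PTA,24,0.28
AK,0,1
AK,1,1
AK,2,1
AK,3,1
AK,4,1
AK,5,1
AK,6,1
AK,7,1
AK,8,0.45
AK,9,0.45
AK,10,0.45
AK,11,0.45
AK,12,0.45
AK,13,0.45
AK,14,0.45
AK,15,0.45
AK,16,0.3
AK,17,0.3
AK,18,0.3
AK,19,0.3
AK,20,0.3
AK,21,0.3
AK,22,0.3
AK,23,0.3
AK,24,0.3
PTB,0,1
PTB,1,1
PTB,2,1
PTB,3,1
PTB,4,1
PTB,5,1
PTB,6,1
PTB,7,1
PTB,8,0.35
PTB,9,0.35
PTB,10,0.35
PTB,11,0.35
PTB,12,0.35
PTB,13,0.35
PTB,14,0.35
PTB,15,0.35
PTB,16,0.25
PTB,17,0.25
PTB,18,0.25
PTB,19,0.25
PTB,20,0.25
PTB,21,0.25
PTB,22,0.25
PTB,23,0.25
PTB,24,0.25
BK,0,1
BK,1,1
BK,2,1
BK,3,1
BK,4,1
BK,5,1
BK,6,1
BK,7,1
BK,8,0.42
BK,9,0.42
BK,10,0.42
BK,11,0.42
BK,12,0.42
BK,13,0.42
BK,14,0.42
BK,15,0.42
BK,16,0.32
BK,17,0.32
BK,18,0.32
BK,19,0.32
BK,20,0.32
BK,21,0.32
BK,22,0.32
BK,23,0.32
BK,24,0.32
CoAT,0,0.18
CoAT,1,0.18
CoAT,2,0.18
CoAT,3,0.18
CoAT,4,0.18
CoAT,5,0.18
CoAT,6,0.18
CoAT,7,0.18
CoAT,8,1
CoAT,9,1
CoAT,10,1
CoAT,11,1
CoAT,12,1
CoAT,13,1
CoAT,14,1
CoAT,15,1
CoAT,16,0.85
CoAT,17,0.85
CoAT,18,0.85
CoAT,19,0.85
CoAT,20,0.85
CoAT,21,0.85
CoAT,22,0.85
CoAT,23,0.85
CoAT,24,0.85
AAD,0,0.12
AAD,1,0.12
AAD,2,0.12
AAD,3,0.12
AAD,4,0.12
AAD,5,0.12
AAD,6,0.12
AAD,7,0.12
AAD,8,1
AAD,9,1
AAD,10,1
AAD,11,1
AAD,12,1
AAD,13,1
AAD,14,1
AAD,15,1
AAD,16,0.8
AAD,17,0.8
AAD,18,0.8
AAD,19,0.8
AAD,20,0.8
AAD,21,0.8
AAD,22,0.8
AAD,23,0.8
AAD,24,0.8
AADC,0,0.15
AADC,1,0.15
AADC,2,0.15
AADC,3,0.15
AADC,4,0.15
AADC,5,0.15
AADC,6,0.15
AADC,7,0.15
AADC,8,1
AADC,9,1
AADC,10,1
AADC,11,1
AADC,12,1
AADC,13,1
AADC,14,1
AADC,15,1
AADC,16,0.9
AADC,17,0.9
AADC,18,0.9
AADC,19,0.9
AADC,20,0.9
AADC,21,0.9
AADC,22,0.9
AADC,23,0.9
AADC,24,0.9
BDH,0,0.04
BDH,1,0.04
BDH,2,0.04
BDH,3,0.04
BDH,4,0.04
BDH,5,0.04
BDH,6,0.04
BDH,7,0.04
BDH,8,1
BDH,9,1
BDH,10,1
BDH,11,1
BDH,12,1
BDH,13,1
BDH,14,1
BDH,15,1
BDH,16,0.85
BDH,17,0.85
BDH,18,0.85
BDH,19,0.85
BDH,20,0.85
BDH,21,0.85
BDH,22,0.85
BDH,23,0.85
BDH,24,0.85
B-C-B,0,1
B-C-B,1,1
B-C-B,2,1
B-C-B,3,1
B-C-B,4,1
B-C-B,5,1
B-C-B,6,1
B-C-B,7,1
B-C-B,8,0.75
B-C-B,9,0.75
B-C-B,10,0.75
B-C-B,11,0.75
B-C-B,12,0.75
B-C-B,13,0.75
B-C-B,14,0.75
B-C-B,15,0.75
B-C-B,16,0.6
B-C-B,17,0.6
B-C-B,18,0.6
B-C-B,19,0.6
B-C-B,20,0.6
B-C-B,21,0.6
B-C-B,22,0.6
B-C-B,23,0.6
B-C-B,24,0.6
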