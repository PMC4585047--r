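region,treatment,time,interaction
ILC,TRUE,FALSE,FALSE
CEA,TRUE,FALSE,FALSE
BNST,TRUE,FALSE,FALSE
CA1,TRUE,FALSE,FALSE
CIN,TRUE,FALSE,FALSE
NACc,TRUE,FALSE,FALSE
SCN,FALSE,TRUE,FALSE
VMH,FALSE,TRUE,FALSE
DMH,FALSE,TRUE,FALSE
PVN,TRUE,TRUE,TRUE
PVT,TRUE,FALSE,TRUE
ARC,TRUE,FALSE,TRUE
CA3,TRUE,TRUE,FALSE
NACs,TRUE,TRUE,FALSE
MEA,FALSE,FALSE,FALSE
BLA,FALSE,FALSE,FALSE
DG,FALSE,FALSE,FALSE
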