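CD163
MRC1
MSR1
CCL17
CCL22
IL10
TGFB1
ARG1
CLEC10A
CD209
MAF
STAB1
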