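IL1B
TNF
CXCL9
CXCL10
CXCL11
CD80
CD86
IL6
IL12B
NOS2
SOCS1
IRF1
IRF5
STAT1
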